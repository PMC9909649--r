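# In-code fixtures: tiny networks, record tables, and CSV writers.

# network from an edge table given as "A->B:3" strings (weight optional)
toy_network <- function(edges, extra_nodes = character(0), is_base = NULL) {
  parsed <- lapply(edges, function(e) {
    m <- regmatches(e, regexec("^(\\w+)->(\\w+)(:(\\d+))?$", e))[[1]]
    list(s = m[2], r = m[3], w = if (nzchar(m[5])) as.integer(m[5]) else 1L)
  })
  arcs <- data.frame(sender = vapply(parsed, `[[`, "", "s"),
                     receiver = vapply(parsed, `[[`, "", "r"),
                     weight = vapply(parsed, `[[`, 1L, "w"),
                     stringsAsFactors = FALSE)
  ids <- sort(unique(c(arcs$sender, arcs$receiver, extra_nodes)))
  nodes <- data.frame(hospital_id = ids, name = ids,
                      region_id = "R01",
                      is_base = if (is.null(is_base)) FALSE else ids %in% is_base,
                      longitude = seq_along(ids), latitude = seq_along(ids),
                      population_served = 1e5, stringsAsFactors = FALSE)
  edtransfernet:::new_transfer_network(nodes, arcs)
}

# network from a 0/1 adjacency matrix (rows = senders)
matrix_network <- function(A, weights = NULL) {
  n <- nrow(A)
  ids <- sprintf("H%02d", seq_len(n))
  idx <- which(A == 1, arr.ind = TRUE)
  arcs <- data.frame(sender = ids[idx[, 1]], receiver = ids[idx[, 2]],
                     weight = if (is.null(weights)) rep(1L, nrow(idx)) else weights,
                     stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$sender, arcs$receiver), , drop = FALSE]
  nodes <- data.frame(hospital_id = ids, name = ids, region_id = "R01",
                      is_base = FALSE, longitude = seq_len(n),
                      latitude = seq_len(n), population_served = 1e5,
                      stringsAsFactors = FALSE)
  edtransfernet:::new_transfer_network(nodes, arcs)
}

random_digraph <- function(n, p) {
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  A
}

adjacency_of <- function(net) {
  ids <- net$nodes$hospital_id
  n <- length(ids)
  A <- matrix(0L, n, n)
  if (nrow(net$arcs))
    A[cbind(match(net$arcs$sender, ids), match(net$arcs$receiver, ids))] <- 1L
  A
}

# minimal well-formed record table
make_records <- function(n, sender = "A", receiver = "B",
                         depart = as.POSIXct("2015-06-15 10:00:00", tz = "UTC")) {
  data.frame(record_id = sprintf("X%05d", seq_len(n)),
             sender_id = rep_len(sender, n), receiver_id = rep_len(receiver, n),
             depart_datetime = rep_len(depart, n),
             arrive_datetime = rep_len(depart, n) + 3600,
             age = 50L, sex = "female", reason = "patient_request",
             condition_category = "pneumonia", surgery_at_receiver = FALSE,
             disposition = "ward_admission", stringsAsFactors = FALSE)
}

small_registry <- function(ids, region = "R01", is_base = FALSE, pop = 1e5) {
  data.frame(hospital_id = ids, name = ids, region_id = rep_len(region, length(ids)),
             is_base = rep_len(is_base, length(ids)),
             longitude = seq_along(ids), latitude = seq_along(ids),
             population_served = rep_len(pop, length(ids)),
             stringsAsFactors = FALSE)
}
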