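# Directed valued transfer networks: construction, thresholding, dyad census.

registry_fields <- function() {
  c("hospital_id", "name", "region_id", "is_base", "longitude", "latitude",
    "population_served")
}

#' Read a hospital registry
#'
#' Reads the hospital registry CSV (columns `id` or `hospital_id`, `name`,
#' `region_id`, `is_base`, `longitude`, `latitude`, `population_served`) and
#' validates identifiers and coordinates.
#'
#' @param path Path to a CSV file with a header row.
#' @return Data frame with the canonical registry columns.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(reg) && !"hospital_id" %in% names(reg))
    names(reg)[names(reg) == "id"] <- "hospital_id"
  missing <- setdiff(c("hospital_id", "region_id", "is_base"), names(reg))
  if (length(missing)) stop("registry lacks column(s): ", paste(missing, collapse = ", "))
  for (f in setdiff(registry_fields(), names(reg))) reg[[f]] <- NA
  reg$hospital_id <- as.character(reg$hospital_id)
  reg$is_base <- as.logical(reg$is_base)
  validate_registry(reg[registry_fields()])
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$hospital_id)) stop("duplicate hospital_id in registry")
  lon <- reg$longitude[!is.na(reg$longitude)]
  lat <- reg$latitude[!is.na(reg$latitude)]
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  reg
}

#' Write a hospital registry CSV
#'
#' @param registry Registry data frame.
#' @param path Output path.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry[registry_fields()], path, row.names = FALSE, na = "")
  invisible(path)
}

new_transfer_network <- function(nodes, arcs, period_label = "") {
  rownames(nodes) <- NULL
  rownames(arcs) <- NULL
  net <- structure(list(nodes = nodes, arcs = arcs, period_label = period_label),
                   class = "transfer_network")
  validate_network(net)
}

validate_network <- function(net) {
  arcs <- net$arcs
  if (nrow(arcs)) {
    if (any(arcs$sender == arcs$receiver)) stop("network contains a self-loop")
    if (any(arcs$weight < 1)) stop("arc weight below 1")
    ids <- net$nodes$hospital_id
    if (!all(arcs$sender %in% ids) || !all(arcs$receiver %in% ids))
      stop("arc endpoint not present among nodes")
    if (anyDuplicated(paste(arcs$sender, arcs$receiver, sep = "\r")))
      stop("duplicate arc (ordered pair)")
  }
  net
}

#' @export
print.transfer_network <- function(x, ...) {
  cat(sprintf("Transfer network%s: %d nodes, %d arcs, %d transfers\n",
              if (nzchar(x$period_label)) paste0(" [", x$period_label, "]") else "",
              nrow(x$nodes), nrow(x$arcs), sum(x$arcs$weight)))
  invisible(x)
}

#' Build a directed valued network from transfer records
#'
#' Aggregates patient-level records into a directed valued graph: one arc per
#' distinct ordered (sender, receiver) hospital pair, weighted by the number of
#' transfers it carries. By default the node set is the hospitals incident to
#' at least one arc; registry isolates can be kept for density sensitivity
#' checks.
#'
#' @param records Data frame of transfer records.
#' @param registry Hospital registry data frame (see [read_registry()]).
#' @param period Optional length-2 vector of POSIXct/Date bounds; records with
#'   departure outside `[period[1], period[2]]` are excluded (right bound
#'   inclusive).
#' @param period_label Label stored on the network.
#' @param include_isolates Keep registry hospitals with no incident arc.
#' @param on_unknown `"error"` (default) fails listing unresolvable hospital
#'   IDs; `"drop"` discards those records with a message.
#' @return A `transfer_network`.
#' @export
build_network <- function(records, registry, period = NULL, period_label = "",
                          include_isolates = FALSE,
                          on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  registry <- validate_registry(registry)
  if (!is.null(period)) {
    lo <- parse_dt(period[1]); hi <- parse_dt(period[2])
    keep <- records$depart_datetime >= lo & records$depart_datetime <= hi
    records <- records[keep, , drop = FALSE]
  }
  known <- registry$hospital_id
  bad <- !(records$sender_id %in% known & records$receiver_id %in% known)
  if (any(bad)) {
    offenders <- sort(unique(c(records$sender_id[!records$sender_id %in% known],
                               records$receiver_id[!records$receiver_id %in% known])))
    if (on_unknown == "error")
      stop("hospital ID(s) not in registry: ", paste(offenders, collapse = ", "))
    message("dropping ", sum(bad), " record(s) with unregistered hospital ID(s)")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records)) {
    key <- paste(records$sender_id, records$receiver_id, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    arcs <- data.frame(sender = vapply(parts, `[`, "", 1),
                       receiver = vapply(parts, `[`, "", 2),
                       weight = as.integer(tab),
                       stringsAsFactors = FALSE)
    arcs <- arcs[order(arcs$sender, arcs$receiver), , drop = FALSE]
  } else {
    arcs <- data.frame(sender = character(), receiver = character(),
                       weight = integer(), stringsAsFactors = FALSE)
  }
  keep_ids <- if (include_isolates) known else unique(c(arcs$sender, arcs$receiver))
  nodes <- registry[registry$hospital_id %in% keep_ids, , drop = FALSE]
  new_transfer_network(nodes, arcs, period_label)
}

#' Extract the skeleton (tie-strength filtered) network
#'
#' Retains arcs whose weight lies in `[min_weight, max_weight]` and drops
#' nodes left without any incident arc. With the study's conventions,
#' `min_weight = 36` over a 3-year window keeps ties averaging at least one
#' transfer per month; `36--365` are medium ties and `> 365` strong ties.
#'
#' @param net A `transfer_network`.
#' @param min_weight Minimum arc weight retained (>= 1).
#' @param max_weight Optional maximum arc weight retained.
#' @return A `transfer_network` restricted to the surviving arcs and their
#'   incident nodes.
#' @export
extract_skeleton <- function(net, min_weight, max_weight = NULL) {
  if (min_weight < 1) stop("min_weight must be >= 1")
  if (!is.null(max_weight) && max_weight < min_weight)
    stop("max_weight must be >= min_weight")
  keep <- net$arcs$weight >= min_weight
  if (!is.null(max_weight)) keep <- keep & net$arcs$weight <= max_weight
  arcs <- net$arcs[keep, , drop = FALSE]
  ids <- unique(c(arcs$sender, arcs$receiver))
  nodes <- net$nodes[net$nodes$hospital_id %in% ids, , drop = FALSE]
  label <- sprintf("%s weight>=%d%s", net$period_label, min_weight,
                   if (is.null(max_weight)) "" else sprintf(",<=%d", max_weight))
  new_transfer_network(nodes, arcs, trimws(label))
}

#' Dyad census of a directed network
#'
#' Classifies every unordered node pair as mutual (arcs both ways),
#' asymmetric (exactly one arc) or null (no arc).
#'
#' @param net A `transfer_network`.
#' @return A `dyad_census` list: `mutual`, `asymmetric`, `null_pairs`,
#'   `n_nodes`.
#' @export
dyad_census <- function(net) {
  n <- nrow(net$nodes)
  key <- paste(net$arcs$sender, net$arcs$receiver, sep = "\r")
  rev_key <- paste(net$arcs$receiver, net$arcs$sender, sep = "\r")
  n_arcs <- nrow(net$arcs)
  mutual <- sum(rev_key %in% key) / 2L
  asymmetric <- n_arcs - 2L * mutual
  total_pairs <- n * (n - 1) / 2
  census <- structure(
    list(mutual = as.integer(mutual), asymmetric = as.integer(asymmetric),
         null_pairs = as.integer(total_pairs - mutual - asymmetric),
         n_nodes = n),
    class = "dyad_census")
  stopifnot(census$mutual + census$asymmetric + census$null_pairs == total_pairs,
            2L * census$mutual + census$asymmetric == n_arcs)
  census
}

#' @export
print.dyad_census <- function(x, ...) {
  cat(sprintf("Dyad census (%d nodes): mutual %d, asymmetric %d, null %d\n",
              x$n_nodes, x$mutual, x$asymmetric, x$null_pairs))
  invisible(x)
}

#' Slice records into one network per calendar year
#'
#' @param records Data frame of transfer records.
#' @param registry Hospital registry.
#' @param ... Passed to [build_network()].
#' @return Named list of `transfer_network`, one per calendar year of
#'   departure, in chronological order.
#' @export
slice_by_year <- function(records, registry, ...) {
  yr <- format(records$depart_datetime, "%Y", tz = "UTC")
  years <- sort(unique(yr))
  out <- lapply(years, function(y) {
    build_network(records[yr == y, , drop = FALSE], registry,
                  period_label = y, ...)
  })
  stats::setNames(out, years)
}

#' Export / import the weighted edge list
#'
#' The edge-list dialect is a three-column CSV (`sender`, `receiver`,
#' `weight`) sorted by sender then receiver; writing and re-reading is
#' bit-exact.
#'
#' @param net A `transfer_network`.
#' @param path File path.
#' @export
write_edgelist <- function(net, path) {
  arcs <- net$arcs[order(net$arcs$sender, net$arcs$receiver), , drop = FALSE]
  utils::write.csv(arcs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @param registry Optional registry supplying node attributes; when omitted,
#'   minimal nodes are synthesized from the arc endpoints.
#' @param period_label Label stored on the imported network.
#' @return `read_edgelist()` returns a `transfer_network`.
#' @export
read_edgelist <- function(path, registry = NULL, period_label = "") {
  arcs <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  ids <- sort(unique(c(arcs$sender, arcs$receiver)))
  if (is.null(registry)) {
    nodes <- data.frame(hospital_id = ids, name = ids, region_id = NA_character_,
                        is_base = NA, longitude = NA_real_, latitude = NA_real_,
                        population_served = NA_real_, stringsAsFactors = FALSE)
  } else {
    nodes <- registry[registry$hospital_id %in% ids, , drop = FALSE]
    missing <- setdiff(ids, nodes$hospital_id)
    if (length(missing)) stop("edge list references hospitals not in registry: ",
                              paste(missing, collapse = ", "))
  }
  arcs <- arcs[order(arcs$sender, arcs$receiver), , drop = FALSE]
  new_transfer_network(nodes, arcs, period_label)
}

#' Convert a transfer network to an igraph graph
#'
#' Node attributes (name, region, hub flag, coordinates, population) and the
#' arc weights are carried over. Used for GraphML interchange; the package's
#' own statistics are computed natively.
#'
#' @param net A `transfer_network`.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(net) {
  vertices <- net$nodes
  vertices <- data.frame(name = vertices$hospital_id,
                         hospital_name = vertices$name,
                         region_id = as.character(vertices$region_id),
                         is_base = as.logical(vertices$is_base),
                         longitude = vertices$longitude,
                         latitude = vertices$latitude,
                         population_served = vertices$population_served,
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$arcs, directed = TRUE, vertices = vertices)
}

#' Export / import GraphML with node attributes
#'
#' @param net A `transfer_network`.
#' @param path File path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @param period_label Label stored on the imported network.
#' @return `read_graphml()` returns a `transfer_network`.
#' @export
read_graphml <- function(path, period_label = "") {
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(hospital_id = as.character(v$name),
                      name = v$hospital_name,
                      region_id = v$region_id,
                      is_base = as.logical(v$is_base),
                      longitude = as.numeric(v$longitude),
                      latitude = as.numeric(v$latitude),
                      population_served = as.numeric(v$population_served),
                      stringsAsFactors = FALSE)
  arcs <- data.frame(sender = as.character(e$from),
                     receiver = as.character(e$to),
                     weight = as.integer(e$weight), stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$sender, arcs$receiver), , drop = FALSE]
  new_transfer_network(nodes, arcs, period_label)
}
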