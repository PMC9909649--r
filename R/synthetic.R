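# Synthetic regionalized hub-and-spoke transfer data with a ground-truth
# ledger, so every pipeline stage is testable without the restricted national
# registry.
#
# The generator is receiver-driven: each hospital gets a planned number of
# distinct transfer-in partners that is linear in its served population
# (slope = target_slope per million residents), which concentrates in-degree
# on the high-population base hospitals; senders are then drawn with a
# same-region preference. Reciprocity is planted exactly by adding weak
# reverse arcs to (or demoting) a fixed fraction of connected dyads.

#' Generator configuration
#'
#' Builds the configuration for [generate_registry()] and
#' [generate_transfers()]. Calibration defaults live in
#' `inst/extdata/generator_defaults.yaml`; a user YAML file and then named
#' arguments override them key by key.
#'
#' @param config_file Optional YAML file with overrides.
#' @param ... Named overrides of individual keys (e.g. `seed = 7`,
#'   `n_regions = 4`).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(config_file = NULL, ...) {
  cfg <- yaml::read_yaml(system.file("extdata", "generator_defaults.yaml",
                                     package = "edtransfernet"))
  override <- function(base, upd) {
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- override(base[[k]], upd[[k]])
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  if (!is.null(config_file)) cfg <- override(cfg, yaml::read_yaml(config_file))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown generator option(s): ",
                              paste(unknown, collapse = ", "))
    cfg <- override(cfg, dots)
  }
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$n_base_per_region >= 1,
            length(cfg$hospitals_per_region) == 2,
            cfg$hospitals_per_region[1] >= cfg$n_base_per_region + 1,
            cfg$hub_attachment_strength >= 0,
            cfg$yearly_growth > 0, length(cfg$years) >= 1)
  if (cfg$reciprocity_target < 0 || cfg$reciprocity_target > 1)
    stop("reciprocity_target must lie in [0, 1]")
  for (nm in names(cfg$record_attribute_tables)) {
    p <- unlist(cfg$record_attribute_tables[[nm]])
    if (abs(sum(p) - 1) > 1e-3)
      stop("attribute table '", nm, "' does not sum to 1")
    cfg$record_attribute_tables[[nm]] <- p / sum(p)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic hospital registry
#'
#' Region centroids are spread on a jittered grid over an abstract planar
#' bounding box (coordinates are degrees but not real geography); hospitals
#' scatter around their region centroid, with the designated base hospitals
#' closest to it. Base hospitals serve large populations (they anchor the
#' planted population/in-degree relationship); spokes serve small ones.
#'
#' @param config A `generator_config`.
#' @return Registry data frame (see [read_registry()] for the columns).
#' @export
generate_registry <- function(config = generator_config()) {
  set.seed(config$seed)
  k <- config$n_regions
  side <- ceiling(sqrt(k))
  gx <- ((seq_len(k) - 1) %% side) * (10 / side) + 5 / side
  gy <- ((seq_len(k) - 1) %/% side) * (10 / side) + 5 / side
  cx <- gx + stats::runif(k, -0.3, 0.3)
  cy <- gy + stats::runif(k, -0.3, 0.3)

  rows <- lapply(seq_len(k), function(r) {
    lo <- config$hospitals_per_region[1]
    hi <- config$hospitals_per_region[2]
    n_h <- lo + sample.int(hi - lo + 1, 1) - 1  # safe when lo == hi
    is_base <- c(rep(TRUE, config$n_base_per_region),
                 rep(FALSE, n_h - config$n_base_per_region))
    jitter_sd <- ifelse(is_base, 0.05, 0.45)
    pop <- ifelse(is_base,
                  stats::runif(n_h, config$base_population_range[1],
                               config$base_population_range[2]),
                  stats::runif(n_h, config$population_range[1],
                               config$population_range[2]))
    data.frame(region_idx = r, is_base = is_base,
               longitude = cx[r] + stats::rnorm(n_h, 0, jitter_sd),
               latitude = cy[r] + stats::rnorm(n_h, 0, jitter_sd),
               population_served = round(pop), stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  reg$hospital_id <- sprintf("H%03d", seq_len(nrow(reg)))
  reg$region_id <- sprintf("R%02d", reg$region_idx)
  reg$name <- sprintf("%s Hospital %s", ifelse(reg$is_base, "Base", "District"),
                      reg$hospital_id)
  reg$longitude <- pmin(pmax(reg$longitude, -180), 180)
  reg$latitude <- pmin(pmax(reg$latitude, -90), 90)
  validate_registry(reg[registry_fields()])
}

# plan the directed arc structure: planned in-degrees linear in population,
# senders drawn with same-region (and same-region-hub) preference
plan_arcs <- function(registry, config) {
  n <- nrow(registry)
  pop_m <- registry$population_served / 1e6
  planned_in <- round(config$in_degree_intercept +
                        config$target_slope * pop_m +
                        stats::rnorm(n, 0, config$in_degree_noise_sd))
  planned_in <- pmin(pmax(planned_in, 0L), n - 1L)

  send <- integer(0); recv <- integer(0)
  for (r in seq_len(n)) {
    d <- planned_in[r]
    if (d == 0) next
    cand <- setdiff(seq_len(n), r)
    same <- registry$region_id[cand] == registry$region_id[r]
    w <- 1 + config$region_affinity * same +
      config$hub_attachment_strength * same * registry$is_base[r]
    chosen <- sample(cand, d, prob = w)
    send <- c(send, chosen)
    recv <- c(recv, rep(r, d))
  }
  arcs <- data.frame(sender = registry$hospital_id[send],
                     receiver = registry$hospital_id[recv],
                     s = send, r = recv, stringsAsFactors = FALSE)

  # draw heavy-tailed weights; spoke -> same-region hub arcs run heavier
  hub_arc <- registry$is_base[arcs$r] &
    registry$region_id[arcs$s] == registry$region_id[arcs$r]
  wd <- config$weight_distribution
  meanlog <- ifelse(hub_arc, wd$hub_meanlog, wd$meanlog)
  sdlog <- ifelse(hub_arc, wd$hub_sdlog, wd$sdlog)
  arcs$weight <- pmax(1L, as.integer(round(stats::rlnorm(nrow(arcs),
                                                         meanlog, sdlog))))

  # plant dyadic reciprocity exactly: mutualize (or demote) dyads to hit
  # round(target * non-null dyads) mutual pairs
  key <- paste(arcs$sender, arcs$receiver, sep = "\r")
  rev_key <- paste(arcs$receiver, arcs$sender, sep = "\r")
  is_mutual_arc <- rev_key %in% key
  pair_key <- ifelse(arcs$sender < arcs$receiver, key, rev_key)
  nonnull <- length(unique(pair_key))
  m_target <- round(config$reciprocity_target * nonnull)
  mutual_pairs <- unique(pair_key[is_mutual_arc])
  m0 <- length(mutual_pairs)

  if (m0 > m_target) {
    demote <- sample(mutual_pairs, m0 - m_target)
    drop_idx <- vapply(demote, function(pk) {
      idx <- which(pair_key == pk)
      idx[which.min(arcs$weight[idx])]  # drop the weaker direction
    }, integer(1))
    arcs <- arcs[-drop_idx, , drop = FALSE]
  } else if (m_target > m0) {
    asym_pairs <- setdiff(unique(pair_key), mutual_pairs)
    promote <- sample(asym_pairs, min(m_target - m0, length(asym_pairs)))
    idx <- match(promote, pair_key)
    reverse <- data.frame(sender = arcs$receiver[idx],
                          receiver = arcs$sender[idx],
                          s = arcs$r[idx], r = arcs$s[idx],
                          weight = sample(seq_len(config$reverse_weight_max),
                                          length(idx), replace = TRUE),
                          stringsAsFactors = FALSE)
    arcs <- rbind(arcs, reverse)
  }
  arcs <- arcs[order(arcs$sender, arcs$receiver),
               c("sender", "receiver", "weight")]
  rownames(arcs) <- NULL
  list(arcs = arcs, nonnull_dyads = nonnull, mutual_planned = min(m_target, nonnull))
}

sample_level <- function(n, table) {
  sample(names(table), n, replace = TRUE, prob = unname(table))
}

#' Generate synthetic patient-level transfer records
#'
#' Expands the planned arc structure into one row per transfer: each arc's
#' weight is split across calendar years with probability growing by
#' `yearly_growth`, departure dates are uniform within the year with hours
#' drawn from the configured time-of-day table, and demographic/clinical
#' attributes are sampled from the configured categorical tables. Transfers
#' sent by the planted distributor hospitals (bottom `distributor_quantile`
#' of senders by realized net connectivity) have their probability of direct
#' ED discharge raised by `distributor_discharge_boost`.
#'
#' @param registry Registry from [generate_registry()].
#' @param config A `generator_config`.
#' @return List with `records` (data frame of transfer records) and `ledger`,
#'   a ground-truth list: `arc_pair_counts` (the planted weighted arc table),
#'   `per_year_counts`, `planted_hub_ids`, `planted_distributor_ids`,
#'   `true_slope`, `true_reciprocity`, `true_discharge_rates`.
#' @export
generate_transfers <- function(registry, config = generator_config()) {
  set.seed(config$seed + 1L)
  plan <- plan_arcs(registry, config)
  arcs <- plan$arcs
  tabs <- config$record_attribute_tables

  # planted distributors: bottom quantile of senders by net connectivity
  net_conn <- stats::setNames(rep(0L, nrow(registry)), registry$hospital_id)
  in_deg <- table(arcs$receiver); out_deg <- table(arcs$sender)
  net_conn[names(in_deg)] <- net_conn[names(in_deg)] + as.integer(in_deg)
  net_conn[names(out_deg)] <- net_conn[names(out_deg)] - as.integer(out_deg)
  sender_ids <- sort(unique(arcs$sender))
  nc_s <- net_conn[sender_ids]
  cutoff <- stats::quantile(nc_s, probs = config$distributor_quantile,
                            names = FALSE, type = 1)
  distributor_ids <- sender_ids[nc_s <= cutoff]

  # ties accumulate over time: each arc activates in some year (new partner
  # relationships appear at rate yearly_growth - 1) and persists; its weight
  # is then split over the active years with growing volume
  years <- sort(as.integer(config$years))
  k <- length(years)
  g <- config$yearly_growth
  year_counts <- if (k == 1) {
    matrix(arcs$weight, ncol = 1)
  } else {
    q_active <- c(1, g^(seq_len(k - 1) - 1) * max(g - 1, 0))
    if (sum(q_active[-1]) == 0) q_active <- c(1, rep(0, k - 1))
    activation <- sample.int(k, nrow(arcs), replace = TRUE,
                             prob = q_active / sum(q_active))
    t(vapply(seq_len(nrow(arcs)), function(i) {
      yc <- integer(k)
      act <- seq(activation[i], k)
      p <- g^(act - 1)
      yc[act] <- as.integer(stats::rmultinom(1, arcs$weight[i], p / sum(p)))
      yc
    }, integer(k)))
  }

  arc_idx <- rep(seq_len(nrow(arcs)), times = arcs$weight)
  rec_year <- rep(rep(years, nrow(arcs)), times = as.vector(t(year_counts)))
  n_rec <- length(arc_idx)

  year_start <- as.POSIXct(paste0(rec_year, "-01-01"), tz = "UTC")
  year_days <- ifelse(rec_year %% 4 == 0 & (rec_year %% 100 != 0 | rec_year %% 400 == 0),
                      366L, 365L)
  day <- floor(stats::runif(n_rec) * year_days)
  band <- sample_level(n_rec, tabs$time_of_day)
  hour <- ifelse(band == "07:00-15:00", 7 + floor(stats::runif(n_rec) * 8),
          ifelse(band == "15:00-23:00", 15 + floor(stats::runif(n_rec) * 8),
                 (23 + floor(stats::runif(n_rec) * 8)) %% 24))
  depart <- year_start + day * 86400 + hour * 3600 +
    floor(stats::runif(n_rec) * 3600)
  arrive <- depart + round(stats::runif(n_rec, 1800, 6 * 3600))

  base_disp <- tabs$disposition
  boost <- config$distributor_discharge_boost
  p_disch <- unname(base_disp["discharged_outpatient"])
  boosted_disp <- base_disp
  boosted_disp["discharged_outpatient"] <- p_disch + boost
  others <- setdiff(names(base_disp), "discharged_outpatient")
  boosted_disp[others] <- base_disp[others] *
    (1 - p_disch - boost) / (1 - p_disch)

  from_distributor <- arcs$sender[arc_idx] %in% distributor_ids
  disposition <- character(n_rec)
  disposition[!from_distributor] <- sample_level(sum(!from_distributor), base_disp)
  if (any(from_distributor))
    disposition[from_distributor] <- sample_level(sum(from_distributor), boosted_disp)

  reason <- sample_level(n_rec, tabs$reason)
  reason[stats::runif(n_rec) < config$reason_missing_rate] <- NA_character_

  records <- data.frame(
    record_id = sprintf("T%07d", seq_len(n_rec)),
    sender_id = arcs$sender[arc_idx],
    receiver_id = arcs$receiver[arc_idx],
    depart_datetime = depart,
    arrive_datetime = arrive,
    age = pmin(pmax(as.integer(round(stats::rnorm(n_rec, config$age_mean,
                                                  config$age_sd))), 0L),
               as.integer(config$age_max)),
    sex = sample_level(n_rec, tabs$sex),
    reason = reason,
    condition_category = sample_level(n_rec, tabs$condition_category),
    surgery_at_receiver = sample_level(n_rec, tabs$surgery_at_receiver) == "yes",
    disposition = disposition,
    stringsAsFactors = FALSE)
  ord <- order(records$depart_datetime, records$record_id)
  records <- records[ord, , drop = FALSE]
  records$record_id <- sprintf("T%07d", seq_len(n_rec))  # id order = time order
  rownames(records) <- NULL

  ledger <- list(
    arc_pair_counts = arcs,
    per_year_counts = stats::setNames(as.integer(colSums(year_counts)),
                                      as.character(years)),
    planted_hub_ids = registry$hospital_id[registry$is_base],
    planted_distributor_ids = distributor_ids,
    true_slope = config$target_slope,
    true_reciprocity = if (plan$nonnull_dyads > 0)
      plan$mutual_planned / plan$nonnull_dyads else NA_real_,
    true_discharge_rates = c(distributor = unname(p_disch) + boost,
                             other = unname(p_disch)))
  stopifnot(sum(ledger$per_year_counts) == nrow(records),
            sum(arcs$weight) == nrow(records))
  list(records = records, ledger = ledger)
}
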