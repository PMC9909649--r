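# Patient-level transfer records: ingest, validation/cleaning, descriptives.

#' Canonical factor levels for transfer-record fields
#'
#' Levels used by [read_transfers()] when validating coded fields. Values not
#' in these sets are nullified (set to `NA`) during cleaning.
#'
#' @name record-levels
#' @keywords internal
NULL

sex_levels <- function() c("female", "male", "unknown")

reason_levels <- function() {
  c("patient_request", "specialist_unavailable", "capability_problem", "other")
}

disposition_levels <- function() {
  c("ward_admission", "ed_observation", "icu_admission",
    "discharged_outpatient", "transferred_again", "transferred_back")
}

# canonical columns of a transfer-record data frame
record_fields <- function() {
  c("record_id", "sender_id", "receiver_id", "depart_datetime",
    "arrive_datetime", "age", "sex", "reason", "condition_category",
    "surgery_at_receiver", "disposition")
}

mandatory_fields <- function() {
  c("record_id", "sender_id", "receiver_id", "depart_datetime")
}

# vectorized, NA (not error) on unparseable values
parse_dt <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    need <- is.na(out) & !is.na(x)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read and clean patient-level transfer records
#'
#' Reads a delimited file of one-row-per-transfer records, maps source columns
#' to the canonical record fields, and applies the validation rules: a transfer
#' must have distinct sender and receiver identifiers and a parseable departure
#' time (otherwise the row is dropped); an arrival time earlier than departure,
#' an age outside 0--130, or an unrecognized coded value is set to missing
#' ("nullified") and counted, but the row is retained; duplicated `record_id`s
#' keep their first occurrence.
#'
#' @param path Path to a CSV (comma) or TSV (tab) file with a header row.
#' @param schema_config Named list or vector mapping canonical field names
#'   (see [record_fields()]) to source column names. Fields omitted from the
#'   mapping are looked up under their canonical name; optional fields absent
#'   from the file are filled with `NA`. The mapping (or the file itself) must
#'   cover `record_id`, `sender_id`, `receiver_id` and `depart_datetime`.
#' @param sep Field separator; defaults from the file extension
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' @return A list with elements `records` (a data frame with the canonical
#'   columns, one row per retained transfer) and `report` (a `cleaning_report`
#'   with `rows_read`, `rows_retained`, `rows_dropped` by rule,
#'   `duplicate_ids_dropped` and per-field `fields_nullified` counts).
#' @seealso [summarize_transfers()], [write_transfers()]
#' @export
read_transfers <- function(path, schema_config = NULL, sep = NULL) {
  if (!file.exists(path)) stop("transfer file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = c("NA", ""))

  schema <- as.list(schema_config)
  cols <- stats::setNames(as.list(record_fields()), record_fields())
  for (f in names(schema)) {
    if (!f %in% record_fields()) stop("unknown canonical field in schema_config: ", f)
    cols[[f]] <- schema[[f]]
  }
  for (f in mandatory_fields()) {
    if (!cols[[f]] %in% names(raw)) {
      stop("mandatory column missing from input: field '", f,
           "' expected in source column '", cols[[f]], "'")
    }
  }

  get_col <- function(f) {
    src <- cols[[f]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }

  n_read <- nrow(raw)
  nullified <- stats::setNames(integer(length(record_fields())), record_fields())

  rec <- data.frame(
    record_id = as.character(get_col("record_id")),
    sender_id = as.character(get_col("sender_id")),
    receiver_id = as.character(get_col("receiver_id")),
    stringsAsFactors = FALSE
  )
  rec$depart_datetime <- suppressWarnings(parse_dt(get_col("depart_datetime")))
  rec$arrive_datetime <- suppressWarnings(parse_dt(get_col("arrive_datetime")))
  rec$age <- suppressWarnings(as.integer(round(as.numeric(get_col("age")))))
  rec$sex <- get_col("sex")
  rec$reason <- get_col("reason")
  rec$condition_category <- get_col("condition_category")
  rec$surgery_at_receiver <- parse_logical(get_col("surgery_at_receiver"))
  rec$disposition <- get_col("disposition")

  # row-level drops: endpoints and departure time are structural
  bad_endpoint <- is.na(rec$sender_id) | is.na(rec$receiver_id)
  self_transfer <- !bad_endpoint & rec$sender_id == rec$receiver_id
  bad_depart <- is.na(rec$depart_datetime)
  drop <- bad_endpoint | self_transfer | bad_depart
  dropped <- c(missing_endpoint = sum(bad_endpoint),
               self_transfer = sum(self_transfer),
               bad_depart_time = sum(bad_depart & !bad_endpoint & !self_transfer))
  rec <- rec[!drop, , drop = FALSE]

  dup <- duplicated(rec$record_id)
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  nullify <- function(field, bad) {
    bad[is.na(bad)] <- FALSE
    nullified[[field]] <<- nullified[[field]] + sum(bad)
    bad
  }

  bad <- nullify("arrive_datetime",
                 !is.na(rec$arrive_datetime) &
                   rec$arrive_datetime < rec$depart_datetime)
  rec$arrive_datetime[bad] <- as.POSIXct(NA, tz = "UTC")

  bad <- nullify("age", !is.na(rec$age) & (rec$age < 0 | rec$age > 130))
  rec$age[bad] <- NA_integer_

  for (spec in list(list("sex", sex_levels()),
                    list("reason", reason_levels()),
                    list("disposition", disposition_levels()))) {
    f <- spec[[1]]
    v <- rec[[f]]
    v[!is.na(v) & v == "missing"] <- NA_character_
    bad <- !is.na(v) & !v %in% spec[[2]]
    if (any(bad)) {
      warning(sum(bad), " unrecognized '", f, "' code(s) set to missing",
              call. = FALSE)
      nullified[[f]] <- nullified[[f]] + sum(bad)
      v[bad] <- NA_character_
    }
    rec[[f]] <- v
  }

  rownames(rec) <- NULL
  report <- structure(
    list(rows_read = n_read,
         rows_retained = nrow(rec),
         rows_dropped = dropped,
         duplicate_ids_dropped = n_dup,
         fields_nullified = nullified[nullified > 0]),
    class = "cleaning_report")
  stopifnot(report$rows_retained <= report$rows_read)
  list(records = rec, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Transfer record cleaning report\n")
  cat("  rows read:     ", x$rows_read, "\n")
  cat("  rows retained: ", x$rows_retained, "\n")
  for (nm in names(x$rows_dropped)) {
    if (x$rows_dropped[[nm]] > 0)
      cat("  dropped (", nm, "): ", x$rows_dropped[[nm]], "\n", sep = "")
  }
  if (x$duplicate_ids_dropped > 0)
    cat("  duplicate record_id dropped:", x$duplicate_ids_dropped, "\n")
  if (length(x$fields_nullified)) {
    cat("  fields nullified:\n")
    for (nm in names(x$fields_nullified))
      cat("    ", nm, ": ", x$fields_nullified[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Write transfer records in the canonical CSV dialect
#'
#' Writes the canonical columns with ISO timestamps so that reading the file
#' back with [read_transfers()] reproduces the records exactly.
#'
#' @param records Data frame of transfer records.
#' @param path Output path.
#' @export
write_transfers <- function(records, path) {
  out <- records[record_fields()]
  out$depart_datetime <- format(out$depart_datetime, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$arrive_datetime <- ifelse(is.na(out$arrive_datetime), NA,
                                format(out$arrive_datetime, "%Y-%m-%d %H:%M:%S",
                                       tz = "UTC"))
  out$surgery_at_receiver <- ifelse(is.na(out$surgery_at_receiver), NA,
                                    ifelse(out$surgery_at_receiver, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Departure time-of-day band
#'
#' Maps a departure hour to the three shift bands used in the descriptive
#' summary: day (7 a.m. to 3 p.m.), evening (3 p.m. to 11 p.m.) and night
#' (11 p.m. to 7 a.m.). A boundary instant belongs to the band it opens.
#'
#' @param hour Integer hour of day, 0--23.
#' @return Character band label.
#' @export
time_of_day_band <- function(hour) {
  ifelse(hour >= 7 & hour < 15, "07:00-15:00",
         ifelse(hour >= 15 & hour < 23, "15:00-23:00", "23:00-07:00"))
}

season_of_month <- function(month) {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "fall", "fall", "fall", "winter")[month]
}

count_table <- function(x, levels = NULL, digits = 1) {
  x <- x[!is.na(x)]
  if (is.null(levels)) levels <- sort(unique(x))
  cnt <- as.integer(table(factor(x, levels = levels)))
  denom <- length(x)
  data.frame(level = levels, count = cnt,
             percent = if (denom > 0) round(100 * cnt / denom, digits) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Descriptive summary of transfer records
#'
#' Produces the descriptive layer of the analysis: total transfer count,
#' mean/SD age over non-missing ages, and count/percent tables for sex,
#' departure time-of-day band, weekend departure, season, transfer reason,
#' condition category, surgery at the receiving hospital, and disposition.
#' Percentages use each variable's non-missing denominator and are rounded to
#' one decimal; the reason denominator (rows with a recorded reason) is
#' reported separately.
#'
#' @param records Data frame of transfer records from [read_transfers()] or
#'   [generate_transfers()].
#' @return A `transfer_summary` list: `n_transfers`, `age_mean`, `age_sd`,
#'   `categorical_tables` (named list of level/count/percent data frames) and
#'   `reason_denominator`.
#' @export
summarize_transfers <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no transfer records to summarize")
  hr <- as.integer(format(records$depart_datetime, "%H", tz = "UTC"))
  wday <- format(records$depart_datetime, "%u", tz = "UTC")  # 1=Mon..7=Sun
  month <- as.integer(format(records$depart_datetime, "%m", tz = "UTC"))

  tables <- list(
    sex = count_table(records$sex, sex_levels()),
    time_of_day = count_table(time_of_day_band(hr),
                              c("07:00-15:00", "15:00-23:00", "23:00-07:00")),
    weekend = count_table(ifelse(wday %in% c("6", "7"), "weekend", "weekday"),
                          c("weekday", "weekend")),
    season = count_table(season_of_month(month),
                         c("spring", "summer", "fall", "winter")),
    reason = count_table(records$reason, reason_levels()),
    condition_category = count_table(records$condition_category),
    surgery_at_receiver = count_table(
      ifelse(records$surgery_at_receiver, "yes", "no"), c("no", "yes")),
    disposition = count_table(records$disposition, disposition_levels())
  )

  ages <- records$age[!is.na(records$age)]
  structure(
    list(n_transfers = nrow(records),
         age_mean = if (length(ages)) mean(ages) else NA_real_,
         age_sd = if (length(ages) > 1) stats::sd(ages) else NA_real_,
         categorical_tables = tables,
         reason_denominator = sum(!is.na(records$reason))),
    class = "transfer_summary")
}

#' Flatten a transfer summary to one row per variable level
#'
#' @param x A `transfer_summary`.
#' @param ... Unused.
#' @return Data frame with columns `variable`, `level`, `count`, `percent`.
#' @export
as.data.frame.transfer_summary <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$categorical_tables), function(v) {
    tab <- x$categorical_tables[[v]]
    cbind(variable = rep(v, nrow(tab)), tab)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.transfer_summary <- function(x, ...) {
  cat(sprintf("Transfers: %d\n", x$n_transfers))
  if (!is.na(x$age_mean))
    cat(sprintf("Age, mean (SD): %.1f (%.1f)\n", x$age_mean, x$age_sd))
  cat(sprintf("Reason recorded for %d transfers\n", x$reason_denominator))
  for (v in names(x$categorical_tables)) {
    tab <- x$categorical_tables[[v]]
    cat(v, ", n (%):\n", sep = "")
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-28s %8d (%.1f)\n", tab$level[i], tab$count[i], tab$percent[i]))
  }
  invisible(x)
}

#' Interhospital transfer rate
#'
#' Transfers as a percentage of all ED visits over the same period.
#'
#' @param n_transfers Number of transfers.
#' @param n_ed_visits Number of ED visits (must be positive).
#' @return Percentage, `100 * n_transfers / n_ed_visits`.
#' @export
transfer_rate <- function(n_transfers, n_ed_visits) {
  if (length(n_ed_visits) != 1 || is.na(n_ed_visits) || n_ed_visits <= 0)
    stop("n_ed_visits must be a positive count")
  100 * n_transfers / n_ed_visits
}
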