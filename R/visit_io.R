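#' Column dialect for visit logs
#'
#' Describes how the six required visit-log fields are named in a CSV file and
#' how its timestamps are formatted. Electronic bin systems export under many
#' column conventions; a dialect maps them onto the canonical names used
#' throughout the package.
#'
#' Timestamps are interpreted as local barn time with a fixed UTC offset
#' (daylight-saving shifts are not modelled; clock times such as the 0500 h
#' milking are taken at face value).
#'
#' @param animal_id,bin_id,bin_type,start,end,intake_kg column names in the file.
#' @param time_format `strptime()` format of the two timestamp columns.
#' @param tz timezone the timestamps are parsed in (default `"UTC"`).
#' @return An object of class `visit_dialect`.
#' @export
visit_dialect <- function(animal_id = "animal_id", bin_id = "bin_id",
                          bin_type = "bin_type", start = "start", end = "end",
                          intake_kg = "intake_kg",
                          time_format = "%Y-%m-%d %H:%M:%S", tz = "UTC") {
  structure(list(animal_id = animal_id, bin_id = bin_id, bin_type = bin_type,
                 start = start, end = end, intake_kg = intake_kg,
                 time_format = time_format, tz = tz),
            class = "visit_dialect")
}

#' Column dialect for climate-logger files
#'
#' @param timestamp,temp_c,rh_pct column names in the file.
#' @param time_format,tz timestamp parsing, as in [visit_dialect()].
#' @return An object of class `climate_dialect`.
#' @export
climate_dialect <- function(timestamp = "timestamp", temp_c = "temp_c",
                            rh_pct = "rh_pct",
                            time_format = "%Y-%m-%d %H:%M:%S", tz = "UTC") {
  structure(list(timestamp = timestamp, temp_c = temp_c, rh_pct = rh_pct,
                 time_format = time_format, tz = tz),
            class = "climate_dialect")
}

#' Read and validate a bin visit log
#'
#' Reads one record per visit of one animal to one electronic bin. Rows that
#' violate the visit invariants are rejected, not repaired: unparseable
#' timestamps, `end <= start`, negative or missing intake, unknown bin type,
#' duplicate `(bin_id, start)` keys, and visits overlapping an earlier visit
#' at the same bin (the hardware admits one cow per bin at a time, so overlap
#' is sensor error; the later-starting row loses). Rejections are returned in
#' the `"rejections"` attribute with the 1-based file line and a reason.
#'
#' @param path path to a CSV file with a header row.
#' @param dialect a [visit_dialect()].
#' @return A `data.frame` with columns `animal_id`, `bin_id`, `bin_type`
#'   (`"drinker"` or `"feeder"`), `start`, `end` (`POSIXct`), `intake_kg`,
#'   sorted by `(bin_id, start)`; attribute `rejections` is a `data.frame`
#'   with columns `line`, `reason`.
#' @export
read_visit_log <- function(path, dialect = visit_dialect()) {
  if (!file.exists(path)) stop("visit log not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(dialect[c("animal_id", "bin_id", "bin_type", "start", "end",
                           "intake_kg")])
  stopifnot_cols(raw, need, "visit log")
  v <- data.frame(
    animal_id = as.character(raw[[dialect$animal_id]]),
    bin_id    = as.character(raw[[dialect$bin_id]]),
    bin_type  = tolower(as.character(raw[[dialect$bin_type]])),
    start     = as.POSIXct(as.character(raw[[dialect$start]]),
                           format = dialect$time_format, tz = dialect$tz),
    end       = as.POSIXct(as.character(raw[[dialect$end]]),
                           format = dialect$time_format, tz = dialect$tz),
    intake_kg = suppressWarnings(as.numeric(raw[[dialect$intake_kg]])),
    stringsAsFactors = FALSE)
  validate_visits(v, line = seq_len(nrow(v)) + 1L)
}

#' Validate an in-memory visit table
#'
#' Applies the same invariant checks as [read_visit_log()] to a table built in
#' code (e.g. by [simulate_herd()]).
#'
#' @param v data.frame with the canonical visit columns.
#' @param line optional original file line numbers for rejection reporting.
#' @return Validated, canonically sorted visits with a `rejections` attribute.
#' @export
validate_visits <- function(v, line = seq_len(nrow(v))) {
  stopifnot_cols(v, c("animal_id", "bin_id", "bin_type", "start", "end",
                      "intake_kg"), "visit table")
  reasons <- character(0); lines <- integer(0)
  reject <- function(idx, why) {
    lines <<- c(lines, line[idx]); reasons <<- c(reasons, rep(why, length(idx)))
  }
  bad_ts <- is.na(v$start) | is.na(v$end)
  reject(which(bad_ts), "unparseable timestamp")
  bad_type <- !bad_ts & !(v$bin_type %in% c("drinker", "feeder"))
  reject(which(bad_type), "unknown bin_type")
  bad_ord <- !bad_ts & !bad_type & as.numeric(v$end) <= as.numeric(v$start)
  reject(which(bad_ord), "end <= start")
  bad_int <- !bad_ts & !bad_type & !bad_ord &
    (is.na(v$intake_kg) | v$intake_kg < 0)
  reject(which(bad_int), "missing or negative intake")
  ok <- !(bad_ts | bad_type | bad_ord | bad_int)

  idx <- which(ok)[order(v$bin_id[ok], v$start[ok], line[ok])]
  # one cow per bin at a time: sweep each bin in start order, reject a row
  # that starts before the last accepted visit at that bin has ended, and
  # duplicate (bin_id, start) keys
  keep <- logical(length(idx))
  last_bin <- ""; last_end <- -Inf; last_start <- -Inf
  for (j in seq_along(idx)) {
    i <- idx[j]
    s <- as.numeric(v$start[i]); e <- as.numeric(v$end[i])
    if (v$bin_id[i] != last_bin) { last_bin <- v$bin_id[i]; last_end <- -Inf; last_start <- -Inf }
    if (s == last_start) { reject(i, "duplicate (bin_id, start)"); next }
    if (s < last_end)    { reject(i, "overlaps previous visit at bin"); next }
    keep[j] <- TRUE; last_end <- e; last_start <- s
  }
  out <- v[idx[keep], , drop = FALSE]
  rownames(out) <- NULL
  rej <- data.frame(line = lines, reason = reasons, stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej[order(rej$line), , drop = FALSE]
  out
}

#' Write a visit log
#'
#' Inverse of [read_visit_log()]: writing then re-reading a valid visit table
#' reproduces it field for field (timestamps at 1-s resolution).
#'
#' @param v validated visit table.
#' @param path output CSV path.
#' @param dialect a [visit_dialect()] naming the output columns.
#' @return `path`, invisibly.
#' @export
write_visit_log <- function(v, path, dialect = visit_dialect()) {
  out <- data.frame(
    a = v$animal_id, b = v$bin_id, t = v$bin_type,
    s = format(v$start, dialect$time_format, tz = dialect$tz),
    e = format(v$end, dialect$time_format, tz = dialect$tz),
    i = v$intake_kg, stringsAsFactors = FALSE)
  names(out) <- unlist(dialect[c("animal_id", "bin_id", "bin_type", "start",
                                 "end", "intake_kg")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a climate-logger file
#'
#' @param path path to a CSV with columns per `dialect` (typically 5-min
#'   temperature / relative-humidity records from a pen logger).
#' @param dialect a [climate_dialect()].
#' @return `data.frame` with `timestamp` (`POSIXct`), `temp_c`, `rh_pct`,
#'   strictly increasing in time; rejected rows (bad humidity, missing values,
#'   duplicate timestamps) in the `rejections` attribute.
#' @export
read_climate_log <- function(path, dialect = climate_dialect()) {
  if (!file.exists(path)) stop("climate log not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(raw, unlist(dialect[c("timestamp", "temp_c", "rh_pct")]),
                 "climate log")
  if (nrow(raw) == 0L) stop("climate log is empty: ", path, call. = FALSE)
  cl <- data.frame(
    timestamp = as.POSIXct(as.character(raw[[dialect$timestamp]]),
                           format = dialect$time_format, tz = dialect$tz),
    temp_c = suppressWarnings(as.numeric(raw[[dialect$temp_c]])),
    rh_pct = suppressWarnings(as.numeric(raw[[dialect$rh_pct]])),
    stringsAsFactors = FALSE)
  line <- seq_len(nrow(cl)) + 1L
  bad <- is.na(cl$timestamp) | is.na(cl$temp_c) | is.na(cl$rh_pct) |
    cl$rh_pct < 0 | cl$rh_pct > 100
  rej <- data.frame(line = line[bad],
                    reason = rep("missing value or rh outside [0,100]", sum(bad)),
                    stringsAsFactors = FALSE)
  cl <- cl[!bad, , drop = FALSE]; line <- line[!bad]
  ord <- order(cl$timestamp, line)
  cl <- cl[ord, , drop = FALSE]; line <- line[ord]
  dup <- duplicated(cl$timestamp)
  if (any(dup))
    rej <- rbind(rej, data.frame(line = line[dup],
                                 reason = "duplicate timestamp",
                                 stringsAsFactors = FALSE))
  cl <- cl[!dup, , drop = FALSE]
  if (nrow(cl) == 0L) stop("climate log has no valid rows: ", path, call. = FALSE)
  rownames(cl) <- NULL
  attr(cl, "rejections") <- rej[order(rej$line), , drop = FALSE]
  cl
}

#' Define a day/bin exclusion rule
#'
#' Analysis periods sometimes contain known bad stretches (e.g. a
#' malfunctioning water bin). A rule excludes all visits whose *start date*
#' falls in the closed date interval, optionally restricted to specific bins
#' (an empty `bin_ids` means all bins).
#'
#' @param start_date,end_date `Date` (or coercible) bounds, inclusive.
#' @param bin_ids character vector of bin ids; empty = every bin.
#' @return An object of class `exclusion_rule`.
#' @export
exclusion_rule <- function(start_date, end_date, bin_ids = character(0)) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date)
    stop("exclusion rule requires start_date <= end_date", call. = FALSE)
  structure(list(start_date = start_date, end_date = end_date,
                 bin_ids = as.character(bin_ids)),
            class = "exclusion_rule")
}

#' Apply exclusion rules to a visit table
#'
#' Removal is idempotent and independent of rule order: a visit is dropped if
#' *any* rule matches its start date (and bin, for bin-restricted rules).
#'
#' @param v visit table.
#' @param rules a list of [exclusion_rule()] objects (or a single rule).
#' @return The surviving visits; attribute `n_removed` gives the count
#'   removed.
#' @export
apply_exclusions <- function(v, rules = list()) {
  if (inherits(rules, "exclusion_rule")) rules <- list(rules)
  drop <- rep(FALSE, nrow(v))
  if (length(rules)) {
    d <- visit_date(v$start)
    for (r in rules) {
      if (!inherits(r, "exclusion_rule")) stop("rules must be exclusion_rule objects")
      m <- d >= r$start_date & d <= r$end_date
      if (length(r$bin_ids)) m <- m & v$bin_id %in% r$bin_ids
      drop <- drop | m
    }
  }
  out <- v[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}
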