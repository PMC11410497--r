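#' Per-cow daily drinking behaviour
#'
#' Sums visit count, time at the drinker and water intake per animal per
#' calendar date (a visit belongs to its start date). Days on which a
#' resident animal never visited count as explicit zero days, so per-cow
#' averages are over resident days, not visit days. Residency comes from the
#' membership table when given; otherwise every animal is assumed resident
#' over the whole date range.
#'
#' @param v visit table; only `bin_type == "drinker"` rows are used.
#' @param membership optional `data.frame` with `animal_id`, `entry_date`,
#'   `exit_date` (`NA` exit = still resident).
#' @param dates optional `Date` vector delimiting the analysed days
#'   (default: the range of visit start dates).
#' @return `data.frame` with `animal_id`, `date`, `n_visits`, `duration_s`,
#'   `intake_kg`, one row per animal-resident-day.
#' @export
daily_behavior <- function(v, membership = NULL, dates = NULL) {
  v <- v[v$bin_type == "drinker", , drop = FALSE]
  if (is.null(dates)) {
    if (nrow(v) == 0L) stop("no drinker visits and no dates supplied", call. = FALSE)
    dr <- range(visit_date(v$start))
    dates <- seq(dr[1], dr[2], by = "day")
  }
  dates <- sort(unique(as.Date(dates)))
  grid <- if (is.null(membership)) {
    animals <- sort(unique(v$animal_id))
    data.frame(animal_id = rep(animals, each = length(dates)),
               date = rep(dates, length(animals)), stringsAsFactors = FALSE)
  } else {
    stopifnot_cols(membership, c("animal_id", "entry_date", "exit_date"),
                   "membership table")
    rows <- lapply(seq_len(nrow(membership)), function(i) {
      lo <- max(as.Date(membership$entry_date[i]), dates[1])
      hi <- min(if (is.na(membership$exit_date[i])) dates[length(dates)]
                else as.Date(membership$exit_date[i]), dates[length(dates)])
      if (lo > hi) return(NULL)
      data.frame(animal_id = membership$animal_id[i],
                 date = seq(lo, hi, by = "day"), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (is.null(grid) || nrow(grid) == 0L)
    stop("no resident animal-days in the requested date range", call. = FALSE)

  d <- visit_date(v$start)
  inside <- d %in% dates
  key_v <- paste(v$animal_id[inside], d[inside])
  dur <- as.numeric(v$end[inside]) - as.numeric(v$start[inside])
  sum_by <- function(x) {
    agg <- tapply(x, key_v, sum)
    stats::setNames(as.numeric(agg), names(agg))
  }
  nv <- sum_by(rep(1, sum(inside)))
  du <- sum_by(dur)
  ik <- sum_by(v$intake_kg[inside])
  key_g <- paste(grid$animal_id, grid$date)
  grid$n_visits <- unname(ifelse(is.na(nv[key_g]), 0, nv[key_g]))
  grid$duration_s <- unname(ifelse(is.na(du[key_g]), 0, du[key_g]))
  grid$intake_kg <- unname(ifelse(is.na(ik[key_g]), 0, ik[key_g]))
  grid <- grid[order(grid$animal_id, grid$date), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Per-cow average daily drinking behaviour
#'
#' Averages the [daily_behavior()] series per animal, optionally split by
#' hot/normal period (days labelled `"undefined"` are dropped). Zero days
#' are included in the mean, so the denominator is resident days.
#'
#' @param daily output of [daily_behavior()].
#' @param periods optional `data.frame` with `date` and `period` (e.g. from
#'   [thi_days()]); when `NULL` a single `"all"` period is used.
#' @return `data.frame` with `animal_id`, `period`, `n_days`, `mean_visits`,
#'   `mean_duration_s`, `mean_intake_kg`.
#' @export
behavior_means <- function(daily, periods = NULL) {
  if (is.null(periods)) {
    daily$period <- "all"
  } else {
    stopifnot_cols(periods, c("date", "period"), "period table")
    daily$period <- periods$period[match(daily$date, periods$date)]
    daily <- daily[!is.na(daily$period) & daily$period != "undefined", ,
                   drop = FALSE]
  }
  if (nrow(daily) == 0L) stop("no days with a defined period", call. = FALSE)
  key <- interaction(daily$animal_id, daily$period, drop = TRUE)
  out <- data.frame(
    animal_id = tapply(daily$animal_id, key, `[`, 1L),
    period = tapply(daily$period, key, `[`, 1L),
    n_days = as.integer(tapply(daily$date, key, length)),
    mean_visits = as.numeric(tapply(daily$n_visits, key, mean)),
    mean_duration_s = as.numeric(tapply(daily$duration_s, key, mean)),
    mean_intake_kg = as.numeric(tapply(daily$intake_kg, key, mean)),
    stringsAsFactors = FALSE)
  out <- out[order(out$period, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diurnal block shares of drinking behaviour
#'
#' Splits the day into `24 / block_hours` blocks anchored at midnight (with
#' the default 4-h blocks: block 0 = 0000-0400 h, ..., block 5 = 2000-2400 h)
#' and computes, per animal and period, the percentage of total visits,
#' drinking duration and water intake falling in each block. A visit belongs
#' to the block containing its start time; visits are not split across block
#' boundaries.
#'
#' Two denominators are supported: `"period-total"` (default) divides block
#' totals by the animal's period total, so shares sum to exactly 100;
#' `"per-day"` computes shares within each day first and averages them over
#' days with a nonzero daily total.
#'
#' @param v visit table; only drinker rows are used.
#' @param periods `data.frame` with `date`, `period`; visits on days with an
#'   undefined period are dropped.
#' @param block_hours block width in hours; must divide 24 (default 4).
#' @param mode `"period-total"` or `"per-day"`.
#' @return `data.frame` with `animal_id`, `period`, `block`, `pct_visits`,
#'   `pct_duration`, `pct_intake`. An animal-period with a zero total for a
#'   metric gets `NA` shares for that metric and is listed in the
#'   `"zero_total"` attribute.
#' @export
block_shares <- function(v, periods, block_hours = 4,
                         mode = c("period-total", "per-day")) {
  mode <- match.arg(mode)
  if (24 %% block_hours != 0) stop("block_hours must divide 24", call. = FALSE)
  n_blocks <- 24L %/% as.integer(block_hours)
  stopifnot_cols(periods, c("date", "period"), "period table")
  v <- v[v$bin_type == "drinker", , drop = FALSE]
  d <- visit_date(v$start)
  per <- periods$period[match(d, periods$date)]
  keep <- !is.na(per) & per != "undefined"
  v <- v[keep, , drop = FALSE]; per <- per[keep]; d <- d[keep]
  if (nrow(v) == 0L) stop("no drinker visits on defined-period days", call. = FALSE)
  hour <- as.numeric(format(v$start, "%H", tz = "UTC")) +
    as.numeric(format(v$start, "%M", tz = "UTC")) / 60
  block <- pmin(floor(hour / block_hours), n_blocks - 1L)
  dur <- as.numeric(v$end) - as.numeric(v$start)

  animals <- sort(unique(v$animal_id))
  pers <- sort(unique(per))
  grid <- expand.grid(animal_id = animals, period = pers,
                      block = seq_len(n_blocks) - 1L, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gkey <- paste(grid$animal_id, grid$period, grid$block)

  tot3 <- function(w, key) {  # sums of metric w by key, zero-filled on gkey
    agg <- tapply(w, key, sum)
    out <- as.numeric(agg[gkey]); out[is.na(out)] <- 0; out
  }
  if (mode == "period-total") {
    key <- paste(v$animal_id, per, block)
    bv <- tot3(rep(1, nrow(v)), key); bd <- tot3(dur, key); bi <- tot3(v$intake_kg, key)
    pkey <- paste(grid$animal_id, grid$period)
    ptot <- function(b) {
      agg <- tapply(b, pkey, sum)
      as.numeric(agg[pkey])
    }
    share <- function(b) {
      tot <- ptot(b)
      ifelse(tot > 0, 100 * b / tot, NA_real_)
    }
    grid$pct_visits <- share(bv)
    grid$pct_duration <- share(bd)
    grid$pct_intake <- share(bi)
  } else {
    # per-day: daily shares averaged over days with a nonzero daily total
    dkey <- paste(v$animal_id, per, d, block)
    ddkey <- paste(v$animal_id, per, d)
    per_metric <- function(w) {
      bday <- tapply(w, dkey, sum)                 # block x day totals
      dtot <- tapply(w, ddkey, sum)                # day totals
      parts <- strsplit(names(bday), " ")
      a <- vapply(parts, `[`, "", 1L); p <- vapply(parts, `[`, "", 2L)
      dt <- vapply(parts, `[`, "", 3L); bl <- vapply(parts, `[`, "", 4L)
      denom <- as.numeric(dtot[paste(a, p, dt)])
      sh <- ifelse(denom > 0, 100 * as.numeric(bday) / denom, NA_real_)
      # average over that animal-period's nonzero days; blocks with no visit
      # on a counted day contribute 0, handled via full day x block grid
      res <- rep(NA_real_, nrow(grid))
      for (i in seq_len(nrow(grid))) {
        ai <- grid$animal_id[i]; pi <- grid$period[i]; bi2 <- as.character(grid$block[i])
        days_i <- unique(dt[a == ai & p == pi])
        days_i <- days_i[as.numeric(dtot[paste(ai, pi, days_i)]) > 0]
        if (!length(days_i)) next
        vals <- sh[a == ai & p == pi & bl == bi2]
        names(vals) <- dt[a == ai & p == pi & bl == bi2]
        full <- stats::setNames(rep(0, length(days_i)), days_i)
        full[names(vals)[names(vals) %in% days_i]] <-
          vals[names(vals) %in% days_i]
        res[i] <- mean(full)
      }
      res
    }
    grid$pct_visits <- per_metric(rep(1, nrow(v)))
    grid$pct_duration <- per_metric(dur)
    grid$pct_intake <- per_metric(v$intake_kg)
  }
  grid <- grid[order(grid$period, grid$animal_id, grid$block), , drop = FALSE]
  rownames(grid) <- NULL
  zero <- unique(paste(grid$animal_id, grid$period)[is.na(grid$pct_visits) |
                                                      is.na(grid$pct_intake)])
  attr(grid, "zero_total") <- zero
  grid
}
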