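#' Temperature-humidity index (THI)
#'
#' NRC-style dry-bulb/relative-humidity THI used across the dairy heat-stress
#' literature:
#' `THI = (1.8*T + 32) - (c1 - c2*RH) * (1.8*T - 26)`
#' with `T` in deg C and `RH` in percent. At `RH = 100` the humidity term
#' vanishes and THI equals the Fahrenheit temperature; at 25 C / 50% RH the
#' index sits at ~71.8, right at the conventional 72 heat-stress threshold
#' for dairy cattle. Coefficients are exposed for alternative THI variants.
#'
#' @param temp_c air temperature, deg C (vectorised).
#' @param rh_pct relative humidity, percent, in \[0, 100\].
#' @param c1,c2 humidity-weight coefficients (defaults 0.55, 0.0055).
#' @return THI values.
#' @export
thi <- function(temp_c, rh_pct, c1 = 0.55, c2 = 0.0055) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("rh_pct must be in [0, 100]", call. = FALSE)
  tf <- 1.8 * temp_c + 32
  tf - (c1 - c2 * rh_pct) * (1.8 * temp_c - 26)
}

#' Daily maximum THI from a climate log
#'
#' @param climate climate table from [read_climate_log()] (or equivalent).
#' @param c1,c2 THI coefficients, see [thi()].
#' @return `data.frame` with `date`, `thi_max`, one row per calendar date
#'   present, date-sorted.
#' @export
thi_daily_max <- function(climate, c1 = 0.55, c2 = 0.0055) {
  stopifnot_cols(climate, c("timestamp", "temp_c", "rh_pct"), "climate table")
  if (nrow(climate) == 0L) stop("empty climate table", call. = FALSE)
  x <- thi(climate$temp_c, climate$rh_pct, c1, c2)
  d <- visit_date(climate$timestamp)
  agg <- tapply(x, d, max)
  out <- data.frame(date = as.Date(names(agg)), thi_max = as.numeric(agg))
  out[order(out$date), , drop = FALSE]
}

#' 3-day trailing average of daily maximum THI
#'
#' Trailing mean over days `d-2, d-1, d`; the first two days are undefined
#' (`NA`) because the window is incomplete. Trailing (rather than centred)
#' alignment means a day's heat-load label never uses future weather.
#'
#' @param daily output of [thi_daily_max()]; dates must be contiguous.
#' @return Input with a `thi_roll3` column added.
#' @export
thi_roll3 <- function(daily) {
  stopifnot_cols(daily, c("date", "thi_max"), "daily THI table")
  daily <- daily[order(daily$date), , drop = FALSE]
  if (nrow(daily) > 1L && any(diff(as.integer(daily$date)) != 1L))
    stop("dates must be contiguous for the rolling average", call. = FALSE)
  x <- daily$thi_max
  daily$thi_roll3 <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 1))
  daily
}

#' Classify days into hot and normal periods
#'
#' A day is `"hot"` when its 3-day trailing average of daily maximum THI is
#' at or above the threshold, `"normal"` when below, and `"undefined"` while
#' the rolling window is incomplete.
#'
#' @param thi_roll3 numeric vector of 3-day rolling THI values (NA allowed).
#' @param threshold heat-stress threshold (default 72).
#' @return Character vector of `"hot"`, `"normal"`, `"undefined"`.
#' @export
classify_thi <- function(thi_roll3, threshold = 72) {
  ifelse(is.na(thi_roll3), "undefined",
         ifelse(thi_roll3 >= threshold, "hot", "normal"))
}

#' Per-day THI table with hot/normal labels
#'
#' Convenience wrapper chaining [thi_daily_max()], [thi_roll3()] and
#' [classify_thi()].
#'
#' @param climate climate table.
#' @param threshold heat-stress threshold (default 72).
#' @param c1,c2 THI coefficients.
#' @return `data.frame` with `date`, `thi_max`, `thi_roll3`, `period`.
#' @export
thi_days <- function(climate, threshold = 72, c1 = 0.55, c2 = 0.0055) {
  d <- thi_roll3(thi_daily_max(climate, c1, c2))
  d$period <- classify_thi(d$thi_roll3, threshold)
  rownames(d) <- NULL
  d
}
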