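#' Configuration for the synthetic herd simulator
#'
#' Defaults describe a dynamic lactating-cow group of the kind the pipeline
#' targets: 48 resident cows sharing 5 electronic water bins and 30 feed
#' bins, group composition exchanged (~6 cows) roughly every 16 days, twice
#' daily milking (~0500, 1500 h) and feed delivery (~0600, 1500 h) driving
#' diurnal visit peaks, a latent dominance order deciding displacement
#' contests, and elevated drinker competition on hot (THI >= 72) days.
#'
#' The contest probabilities are calibrated so the default herd produces on
#' the order of 35-40 drinker replacements per day, the magnitude reported
#' for comparable barns; this is face-validity calibration, not a fitted
#' quantity.
#'
#' @param n_cows resident group size (held constant through turnover).
#' @param n_drinkers,n_feeders number of water and feed bins.
#' @param n_days simulated days.
#' @param start_date first study date.
#' @param turnover_interval_mean,turnover_interval_sd days between group
#'   changes (Gaussian, rounded, min 2).
#' @param turnover_count_mean,turnover_count_sd cows exchanged per change.
#' @param milking_times,feed_times hours of day for milking and feed
#'   delivery; visit intensity peaks shortly after each.
#' @param beta despotism: contests are won by the arriver with probability
#'   `plogis(beta * (d_arriver - d_occupant))`; 0 = coin-flip outcomes,
#'   large beta = near-deterministic wins for the higher-ranked cow.
#' @param drinker_visits_per_day,feeder_visits_per_day mean visits per cow.
#' @param visit_rate_slope relative decrease of drinker visit rate with
#'   latent dominance (dominant cows visit less often).
#' @param intake_slope relative increase of per-second drinking rate with
#'   latent dominance (dominant cows drink more per day).
#' @param drinker_contest_prob,feeder_contest_prob probability that an
#'   arriving cow targets an occupied bin (a contest) rather than a free one.
#' @param hot_multiplier multiplier (>= 1) on the drinker contest
#'   probability on hot days.
#' @param drinker_intake_base,feeder_intake_base mean intake (kg) of a
#'   median-length visit for a mid-ranked cow.
#' @param drinker_duration_meanlog,drinker_duration_sdlog,feeder_duration_meanlog,feeder_duration_sdlog
#'   log-normal visit duration parameters (seconds).
#' @param gap_threshold_s displacement exit-to-entry gap ceiling the
#'   simulator plants (and that detection should use).
#' @param hot_fraction approximate fraction of days classifying hot.
#' @param seed RNG seed.
#' @return A list of class `herd_config`.
#' @export
herd_config <- function(n_cows = 48, n_drinkers = 5, n_feeders = 30,
                        n_days = 112, start_date = as.Date("2020-07-01"),
                        turnover_interval_mean = 16, turnover_interval_sd = 3,
                        turnover_count_mean = 6, turnover_count_sd = 2,
                        milking_times = c(5, 15), feed_times = c(6, 15),
                        beta = 4,
                        drinker_visits_per_day = 8, feeder_visits_per_day = 30,
                        visit_rate_slope = 0.5, intake_slope = 0.8,
                        drinker_contest_prob = 0.38, feeder_contest_prob = 0.5,
                        hot_multiplier = 1.15,
                        drinker_intake_base = 11, feeder_intake_base = 1.5,
                        drinker_duration_meanlog = log(80),
                        drinker_duration_sdlog = 0.4,
                        feeder_duration_meanlog = log(300),
                        feeder_duration_sdlog = 0.5,
                        gap_threshold_s = 26,
                        hot_fraction = 0.46, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_cows >= 2, n_drinkers >= 1, n_days >= 1, beta >= 0,
            hot_multiplier >= 1, hot_fraction >= 0, hot_fraction <= 1,
            gap_threshold_s >= 6)
  structure(cfg, class = "herd_config")
}

#' Generate a synthetic 5-minute climate log
#'
#' Emits 288 records per day: a sinusoidal diurnal temperature with an
#' afternoon (1500 h) peak plus small Gaussian noise, and relative humidity
#' in anti-phase (dry afternoons, humid nights). Daily peak temperatures are
#' chosen so that approximately `hot_fraction` of days classify hot under
#' the 3-day trailing max-THI rule: hot days are laid out as one contiguous
#' block (heat waves are runs of days, and the rolling average needs runs to
#' cross the threshold cleanly).
#'
#' @param n_days number of days.
#' @param hot_fraction target fraction of hot days in \[0, 1\].
#' @param start_date date of the first record.
#' @param seed optional seed (`NULL` = use the current RNG stream).
#' @return Climate `data.frame` (`timestamp`, `temp_c`, `rh_pct`).
#' @export
generate_climate <- function(n_days, hot_fraction = 0.46,
                             start_date = as.Date("2020-07-01"), seed = NULL) {
  stopifnot(hot_fraction >= 0, hot_fraction <= 1, n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_hot <- round(hot_fraction * n_days)
  hot_day <- rep(FALSE, n_days)
  if (n_hot > 0) {
    first <- max(1L, floor((n_days - n_hot) / 2) + 1L)
    hot_day[seq(first, length.out = n_hot)] <- TRUE
  }
  # daily peak THI targets; clipped so pure-normal (or pure-hot) runs cannot
  # cross the 72 threshold through noise alone
  target <- ifelse(hot_day,
                   pmax(74, stats::rnorm(n_days, 76, 1.0)),
                   pmin(70, stats::rnorm(n_days, 66.5, 1.5)))
  # invert THI at the afternoon RH trough (RH = 50): THI = 0.725*Tf + 15.95
  t_peak_c <- ((target - 15.95) / 0.725 - 32) / 1.8

  h <- (seq_len(288) - 1) / 12             # hour of day at 5-min steps
  shape <- (1 - cos(2 * pi * (h - 15) / 24)) / 2   # 0 at 1500 h, 1 at 0300 h
  temp <- rep(t_peak_c, each = 288) - 10 * rep(shape, n_days) +
    stats::rnorm(288 * n_days, 0, 0.25)
  rh <- 65 - 15 * cos(2 * pi * (rep(h, n_days) - 15) / 24)  # 50 at 1500 h
  rh <- pmin(95, pmax(20, rh + stats::rnorm(288 * n_days, 0, 2)))
  base <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  data.frame(
    timestamp = base + (rep(seq_len(n_days) - 1, each = 288) * 86400 +
                          rep((seq_len(288) - 1) * 300, n_days)),
    temp_c = temp, rh_pct = rh, stringsAsFactors = FALSE)
}

# latent dominance values on [0,1], distinct with guaranteed spacing for the
# initial cohort (gap construction), entrants drawn fresh with tie rejection
draw_latent_d <- function(n) {
  eps <- 1 / (2 * n)
  g <- stats::runif(n + 1)
  g <- g / sum(g) * (1 - (n + 1) * eps) + eps
  d <- cumsum(g)[seq_len(n)]
  sample(d)  # random assignment to ids
}

draw_entrant_d <- function(existing, n) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      cand <- stats::runif(1)
      if (all(abs(cand - c(existing, out[seq_len(i - 1)])) > 1e-3)) break
    }
    out[i] <- cand
  }
  out
}

# minute-of-day arrival weights: low baseline with Gaussian bumps after
# milking and feed-delivery times
diurnal_weights <- function(milking_times, feed_times) {
  m <- 0:1439
  w <- rep(0.35, 1440)
  for (pk in c(milking_times * 60 + 40, feed_times * 60 + 30))
    w <- w + 2 * exp(-0.5 * ((m - pk) / 45)^2)
  w
}

#' Simulate a dynamic herd at electronic bins
#'
#' Agent-based generator for the full pipeline input: a visit log (drinkers
#' and feeders), a 5-min climate log, a membership/turnover table, and the
#' ground truth the estimators should recover.
#'
#' Visits arise from a diurnally inhomogeneous arrival process per cow. An
#' arriving cow either targets a free bin (its start pushed so that benign
#' same-bin gaps always exceed the displacement gap threshold) or, with the
#' configured contest probability, targets an occupied bin. A contest is won
#' by the arriver with probability `plogis(beta * (d_i - d_j))` on the
#' latent dominance values; a win truncates the occupant's visit and plants
#' a displacement whose exit-to-entry gap is below the threshold, so the
#' detector can be validated exactly against planted events. Hot days (3-day
#' rolling max THI >= 72 in the generated climate) multiply the drinker
#' contest probability by `hot_multiplier`. Dominant cows visit the drinker
#' less often but drink more per visit, reproducing the sign structure the
#' association analysis looks for. Roster turnover replaces cows at random
#' epochs; entrants get fresh latent dominance values.
#'
#' @param cfg a [herd_config()].
#' @return List with `visits` (validated visit table), `climate`,
#'   `membership` (`animal_id`, `entry_date`, `exit_date`), and `truth`
#'   (latent `d`, planted `events`, `day_periods`, `config`, `seed`).
#' @export
simulate_herd <- function(cfg = herd_config()) {
  stopifnot(inherits(cfg, "herd_config"))
  set.seed(cfg$seed)
  n_days <- cfg$n_days
  start <- as.Date(cfg$start_date)

  # climate starts 2 days early so every study day has a defined period
  climate <- generate_climate(n_days + 2, cfg$hot_fraction, start - 2)
  td <- thi_days(climate)
  study_dates <- seq(start, by = "day", length.out = n_days)
  day_periods <- td[td$date %in% study_dates, c("date", "thi_max",
                                                "thi_roll3", "period")]
  hot_flag <- day_periods$period == "hot"

  # roster and turnover
  id_of <- function(i) sprintf("cow%03d", i)
  n0 <- cfg$n_cows
  all_ids <- id_of(seq_len(n0))
  d_all <- draw_latent_d(n0)
  resident <- rep(TRUE, n0)
  entry <- rep(start, n0)
  exit <- rep(as.Date(NA), n0)
  epochs <- integer(0)
  day <- 0
  repeat {
    day <- day + max(2, round(stats::rnorm(1, cfg$turnover_interval_mean,
                                           cfg$turnover_interval_sd)))
    if (day > n_days) break
    epochs <- c(epochs, day)
  }
  swaps <- lapply(epochs, function(ep) {
    k <- max(1, min(n0 - 1,
                    round(stats::rnorm(1, cfg$turnover_count_mean,
                                       cfg$turnover_count_sd))))
    k
  })

  # arrivals, generated day by day so roster changes take effect
  w_min <- diurnal_weights(cfg$milking_times, cfg$feed_times)
  arr <- list(drinker = list(), feeder = list())
  for (dy in seq_len(n_days)) {
    if (dy %in% epochs) {
      k <- swaps[[match(dy, epochs)]]
      res_idx <- which(resident)
      out_idx <- sample(res_idx, k)
      resident[out_idx] <- FALSE
      exit[out_idx] <- study_dates[dy] - 1
      new_ids <- id_of(length(all_ids) + seq_len(k))
      new_d <- draw_entrant_d(d_all, k)
      all_ids <- c(all_ids, new_ids)
      d_all <- c(d_all, new_d)
      resident <- c(resident, rep(TRUE, k))
      entry <- c(entry, rep(study_dates[dy], k))
      exit <- c(exit, rep(as.Date(NA), k))
    }
    res_idx <- which(resident)
    day0 <- (dy - 1) * 86400
    gen_type <- function(rate_per_cow) {
      n_i <- stats::rpois(length(res_idx), rate_per_cow)
      if (sum(n_i) == 0) return(NULL)
      cow <- rep(res_idx, n_i)
      minute <- sample(0:1439, sum(n_i), replace = TRUE, prob = w_min)
      t <- day0 + minute * 60 + sample(0:59, sum(n_i), replace = TRUE)
      data.frame(t = t, cow = cow)
    }
    if (cfg$drinker_visits_per_day > 0 && cfg$n_drinkers > 0) {
      rate <- cfg$drinker_visits_per_day *
        (1 + cfg$visit_rate_slope * (0.5 - d_all[res_idx]))
      a <- gen_type(rate)
      if (!is.null(a)) { a$hot <- hot_flag[dy]; arr$drinker[[dy]] <- a }
    }
    if (cfg$feeder_visits_per_day > 0 && cfg$n_feeders > 0) {
      a <- gen_type(rep(cfg$feeder_visits_per_day, length(res_idx)))
      if (!is.null(a)) { a$hot <- hot_flag[dy]; arr$feeder[[dy]] <- a }
    }
  }

  base <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  thr <- cfg$gap_threshold_s

  run_bins <- function(arrivals, bin_ids, contest_prob, hot_mult,
                       meanlog, sdlog, dur_range) {
    n <- nrow(arrivals)
    ord <- order(arrivals$t)
    t <- arrivals$t[ord]; cow <- arrivals$cow[ord]; hot <- arrivals$hot[ord]
    p_chal <- pmin(0.95, contest_prob * ifelse(hot, hot_mult, 1))
    chal <- stats::runif(n) < p_chal
    dur <- pmin(dur_range[2], pmax(dur_range[1],
                                   round(stats::rlnorm(n, meanlog, sdlog))))
    gap <- sample(2:(thr - 2), n, replace = TRUE)
    u_win <- stats::runif(n)
    nb <- length(bin_ids)
    occ_cow <- integer(nb); occ_start <- rep(-Inf, nb)
    occ_end <- rep(-Inf, nb); occ_row <- integer(nb)
    v_cow <- integer(n); v_bin <- integer(n)
    v_start <- numeric(n); v_end <- numeric(n)
    e_actor <- integer(n); e_reactor <- integer(n); e_bin <- integer(n)
    e_time <- numeric(n); e_gap <- numeric(n)
    nv <- 0L; ne <- 0L
    for (i in seq_len(n)) {
      ti <- t[i]; ci <- cow[i]
      placed <- FALSE
      if (chal[i]) {
        cand <- which(occ_end > ti & occ_cow != ci & occ_start + 2 <= ti)
        if (length(cand)) {
          b <- sample1(cand)
          opp <- occ_cow[b]
          p_win <- 1 / (1 + exp(-cfg$beta * (d_all[ci] - d_all[opp])))
          if (u_win[i] < p_win) {
            v_end[occ_row[b]] <- ti          # occupant displaced now
            s <- ti + gap[i]
            nv <- nv + 1L
            v_cow[nv] <- ci; v_bin[nv] <- b
            v_start[nv] <- s; v_end[nv] <- s + dur[i]
            ne <- ne + 1L
            e_actor[ne] <- ci; e_reactor[ne] <- opp; e_bin[ne] <- b
            e_time[ne] <- s; e_gap[ne] <- gap[i]
            occ_cow[b] <- ci; occ_start[b] <- s
            occ_end[b] <- s + dur[i]; occ_row[b] <- nv
          }
          placed <- TRUE                     # contest consumed the arrival
        }
      }
      if (!placed) {
        free <- which(occ_end <= ti)
        if (!length(free)) next
        b <- sample1(free)
        s <- if (occ_cow[b] == ci) max(ti, occ_end[b] + 1)
             else max(ti, occ_end[b] + thr + 2)
        nv <- nv + 1L
        v_cow[nv] <- ci; v_bin[nv] <- b
        v_start[nv] <- s; v_end[nv] <- s + dur[i]
        occ_cow[b] <- ci; occ_start[b] <- s
        occ_end[b] <- s + dur[i]; occ_row[b] <- nv
      }
    }
    list(visits = data.frame(cow = v_cow[seq_len(nv)],
                             bin = bin_ids[v_bin[seq_len(nv)]],
                             start = v_start[seq_len(nv)],
                             end = v_end[seq_len(nv)],
                             stringsAsFactors = FALSE),
         events = data.frame(actor = e_actor[seq_len(ne)],
                             reactor = e_reactor[seq_len(ne)],
                             bin = bin_ids[e_bin[seq_len(ne)]],
                             time = e_time[seq_len(ne)],
                             gap_s = e_gap[seq_len(ne)],
                             stringsAsFactors = FALSE))
  }

  pieces <- list(); planted <- list()
  for (bt in c("drinker", "feeder")) {
    a <- do.call(rbind, arr[[bt]])
    if (is.null(a) || nrow(a) == 0L) next
    if (bt == "drinker") {
      res <- run_bins(a, sprintf("D%02d", seq_len(cfg$n_drinkers)),
                      cfg$drinker_contest_prob, cfg$hot_multiplier,
                      cfg$drinker_duration_meanlog, cfg$drinker_duration_sdlog,
                      c(20, 600))
      rate <- cfg$drinker_intake_base / 80 *
        (0.6 + cfg$intake_slope * d_all[res$visits$cow])
    } else {
      res <- run_bins(a, sprintf("F%02d", seq_len(cfg$n_feeders)),
                      cfg$feeder_contest_prob, 1,
                      cfg$feeder_duration_meanlog, cfg$feeder_duration_sdlog,
                      c(30, 1800))
      rate <- cfg$feeder_intake_base / 300 * rep(1, nrow(res$visits))
    }
    v <- res$visits
    if (nrow(v)) {
      intake <- rate * (v$end - v$start) *
        exp(stats::rnorm(nrow(v), 0, 0.15))
      pieces[[bt]] <- data.frame(
        animal_id = all_ids[v$cow], bin_id = v$bin, bin_type = bt,
        start = base + v$start, end = base + v$end,
        intake_kg = round(intake, 3), stringsAsFactors = FALSE)
    }
    e <- res$events
    if (nrow(e))
      planted[[bt]] <- data.frame(
        actor_id = all_ids[e$actor], reactor_id = all_ids[e$reactor],
        bin_id = e$bin, bin_type = bt, time = base + e$time,
        gap_s = e$gap_s, stringsAsFactors = FALSE)
  }
  visits <- validate_visits(do.call(rbind, pieces))
  events <- do.call(rbind, planted)
  if (!is.null(events)) {
    events <- events[order(events$time, events$bin_id), , drop = FALSE]
    rownames(events) <- NULL
  }
  membership <- data.frame(animal_id = all_ids, entry_date = entry,
                           exit_date = exit, latent_d = d_all,
                           stringsAsFactors = FALSE)
  list(visits = visits, climate = climate,
       membership = membership[, c("animal_id", "entry_date", "exit_date")],
       truth = list(d = stats::setNames(d_all, all_ids), events = events,
                    day_periods = day_periods, config = cfg,
                    seed = cfg$seed))
}

#' Recovery metrics against simulator ground truth
#'
#' @param truth `truth` element of a [simulate_herd()] result.
#' @param detected replacement events from [detect_replacements()] (same
#'   bin-type scope as `truth$events`, or filter both).
#' @param dominance a `dominance_summary`, named `S` vector, or `NULL`.
#' @return List with `precision` and `recall` of detection against the
#'   planted events, `n_planted`, `n_detected`, and (if `dominance` given)
#'   `rho_recovery`, the Spearman correlation of latent dominance with the
#'   estimated summed winning probabilities.
#' @export
truth_report <- function(truth, detected, dominance = NULL) {
  key <- function(e) paste(e$bin_id, e$actor_id, e$reactor_id,
                           as.numeric(e$time))
  kp <- key(truth$events); kd <- key(detected)
  tp <- sum(kd %in% kp)
  out <- list(
    precision = if (length(kd)) tp / length(kd) else NA_real_,
    recall = if (length(kp)) tp / length(kp) else NA_real_,
    n_planted = length(kp), n_detected = length(kd))
  if (!is.null(dominance)) {
    S <- get_S(dominance)
    shared <- intersect(names(S), names(truth$d))
    out$rho_recovery <- if (length(shared) >= 3)
      spearman_cor(truth$d[shared], S[shared])$rho else NA_real_
  }
  out
}
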