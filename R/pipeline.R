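stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

read_or_pass <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full dominance / drinking-behaviour analysis
#'
#' Orchestrates every stage end to end and writes a result bundle to
#' `outdir`: replacement events, the per-day THI table, dominance summaries
#' (drinker, feeder, actor-proportionally subsampled feeder, hot-period and
#' normal-period drinker), daily and diurnal-block drinking metrics, the
#' assembled comparison tables, and a JSON manifest echoing the
#' configuration, seed and per-stage counts. Inputs are either file paths /
#' data frames (`visits`, `climate`, `membership`) or a simulator
#' configuration (`sim`), exactly one of the two.
#'
#' Every random stage derives its seed from `seed` plus a fixed offset, so
#' stages are independently reproducible.
#'
#' @param outdir output directory (created if needed).
#' @param visits,climate,membership input paths or data frames.
#' @param sim a [herd_config()] for simulate mode.
#' @param threshold_s replacement gap threshold, seconds.
#' @param exclusions list of [exclusion_rule()] objects.
#' @param r0,k,scale Elo parameters.
#' @param n_rep resampling replicates per dominance summary. The module
#'   default elsewhere is 1000; the pipeline default of 300 keeps a
#'   full-scale run well inside a desktop time budget and changes SD bands
#'   negligibly.
#' @param resample_mode `"shuffle"` or `"bootstrap"`.
#' @param thi_threshold hot/normal THI threshold.
#' @param block_hours diurnal block width.
#' @param adjust_daily BH-adjust the daily-metric correlations.
#' @param seed master seed.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with all stage outputs and the `manifest`.
#' @export
run_analysis <- function(outdir,
                         visits = NULL, climate = NULL, membership = NULL,
                         sim = NULL,
                         threshold_s = 26, exclusions = list(),
                         r0 = 1000, k = 100, scale = 400,
                         n_rep = 300, resample_mode = "shuffle",
                         thi_threshold = 72, block_hours = 4,
                         adjust_daily = FALSE,
                         seed = 1, verbose = TRUE) {
  if (is.null(sim) == is.null(visits))
    stop("supply exactly one of `sim` or `visits` (+ climate)", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = seed, threshold_s = threshold_s,
                   elo = list(r0 = r0, k = k, scale = scale),
                   n_rep = n_rep, resample_mode = resample_mode,
                   thi_threshold = thi_threshold, block_hours = block_hours,
                   package_version = as.character(utils::packageVersion("drinkdom")),
                   counts = list())
  truth <- NULL
  if (!is.null(sim)) {
    say("stage simulate: %d cows, %d days, seed %d", sim$n_cows, sim$n_days,
        sim$seed)
    simres <- stage("simulate", simulate_herd(sim))
    visits <- simres$visits; climate <- simres$climate
    membership <- simres$membership; truth <- simres$truth
    manifest$sim <- sim[c("n_cows", "n_drinkers", "n_feeders", "n_days",
                          "beta", "hot_multiplier", "hot_fraction", "seed")]
  } else {
    visits <- stage("read_visits", read_or_pass(visits, read_visit_log))
    climate <- stage("read_climate", read_or_pass(climate, read_climate_log))
    if (!is.null(membership))
      membership <- stage("read_membership",
                          read_or_pass(membership, function(p)
                            utils::read.csv(p, stringsAsFactors = FALSE,
                                            colClasses = c(entry_date = "Date",
                                                           exit_date = "Date"))))
  }
  manifest$counts$visits_read <- nrow(visits)

  visits <- stage("exclusions", apply_exclusions(visits, exclusions))
  manifest$counts$visits_excluded <- attr(visits, "n_removed")
  manifest$counts$visits_analyzed <- nrow(visits)
  say("stage exclusions: removed %d visits, %d remain",
      attr(visits, "n_removed"), nrow(visits))

  td <- stage("thi", thi_days(climate, threshold = thi_threshold))
  manifest$counts$days_hot <- sum(td$period == "hot")
  manifest$counts$days_normal <- sum(td$period == "normal")
  manifest$counts$days_undefined <- sum(td$period == "undefined")
  say("stage thi: %d hot / %d normal / %d undefined days",
      manifest$counts$days_hot, manifest$counts$days_normal,
      manifest$counts$days_undefined)

  ev <- stage("detect", detect_replacements(visits, threshold_s))
  ev_d <- ev[ev$bin_type == "drinker", , drop = FALSE]
  ev_f <- ev[ev$bin_type == "feeder", , drop = FALSE]
  if (nrow(ev_d) == 0L)
    stop("stage [detect]: no drinker replacement events", call. = FALSE)
  manifest$counts$replacements_drinker <- nrow(ev_d)
  manifest$counts$replacements_feeder <- nrow(ev_f)
  say("stage detect: %d drinker / %d feeder replacements", nrow(ev_d),
      nrow(ev_f))

  ev_date <- visit_date(ev_d$time)
  per_of <- td$period[match(ev_date, td$date)]
  ev_hot <- ev_d[!is.na(per_of) & per_of == "hot", , drop = FALSE]
  ev_nor <- ev_d[!is.na(per_of) & per_of == "normal", , drop = FALSE]

  ev_fsub <- NULL
  if (nrow(ev_f) > nrow(ev_d))
    ev_fsub <- stage("subsample",
                     subsample_proportional(ev_f, nrow(ev_d), seed = seed + 1L))
  else if (nrow(ev_f) > 0L) ev_fsub <- ev_f
  manifest$counts$replacements_feeder_subsampled <-
    if (is.null(ev_fsub)) 0L else nrow(ev_fsub)

  summarise <- function(e, off) {
    if (is.null(e) || nrow(e) < 2L || length(unique(c(e$actor_id, e$reactor_id))) < 2L)
      return(NULL)
    elo_summary(e, n_rep = n_rep, mode = resample_mode, seed = seed + off,
                r0 = r0, k = k, scale = scale)
  }
  say("stage hierarchy: Elo + %d x %s resampling", n_rep, resample_mode)
  dom <- stage("hierarchy", list(
    drinker = summarise(ev_d, 10L),
    feeder = summarise(ev_f, 11L),
    feeder_sub = summarise(ev_fsub, 12L),
    hot = summarise(ev_hot, 13L),
    normal = summarise(ev_nor, 14L)))
  dom <- dom[!vapply(dom, is.null, TRUE)]

  defined_dates <- td$date[td$period != "undefined"]
  say("stage metrics: daily behaviour and %d-h block shares", block_hours)
  daily <- stage("metrics", daily_behavior(visits, membership,
                                           dates = defined_dates))
  means <- stage("metrics", behavior_means(daily, td))
  blocks <- stage("metrics", block_shares(visits, td, block_hours))

  repl_days <- stage("metrics", {
    dd <- defined_dates[defined_dates >= min(visit_date(visits$start)) &
                          defined_dates <= max(visit_date(visits$start))]
    cnt <- table(factor(as.character(ev_date), levels = as.character(dd)))
    data.frame(date = dd, period = td$period[match(dd, td$date)],
               n_events = as.integer(cnt), stringsAsFactors = FALSE)
  })

  say("stage associate: correlations, BH adjustment, Welch test")
  dom_for_stats <- dom[intersect(names(dom), c("drinker", "hot", "normal"))]
  if (!is.null(dom$feeder_sub)) dom_for_stats$feeder <- dom$feeder_sub
  else if (!is.null(dom$feeder)) dom_for_stats$feeder <- dom$feeder
  comp <- stage("associate",
                assemble_comparisons(dom_for_stats, means, blocks, repl_days,
                                     adjust_daily = adjust_daily))
  manifest$counts$correlations <- nrow(comp$correlations)

  say("stage write: %s", outdir)
  wcsv <- function(x, f) utils::write.csv(x, file.path(outdir, f),
                                          row.names = FALSE)
  ev_out <- ev; ev_out$time <- format(ev_out$time, "%Y-%m-%d %H:%M:%S",
                                      tz = "UTC")
  wcsv(ev_out, "replacements.csv")
  wcsv(td, "thi_days.csv")
  steep <- list()
  for (nm in names(dom)) {
    wcsv(dom[[nm]]$animals, sprintf("dominance_%s.csv", nm))
    steep[[nm]] <- dom[[nm]]$steepness
  }
  jsonlite::write_json(steep, file.path(outdir, "steepness.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wcsv(daily, "daily_behavior.csv")
  wcsv(means, "behavior_means.csv")
  wcsv(blocks, "block_shares.csv")
  wcsv(repl_days, "replacement_days.csv")
  wcsv(comp$correlations, "correlations.csv")
  if (!is.null(comp$welch)) wcsv(comp$welch, "welch.csv")
  if (!is.null(truth)) {
    gt <- list(d = as.list(truth$d), seed = truth$seed,
               n_planted_events = nrow(truth$events),
               day_periods = truth$day_periods)
    jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(visits = visits, thi_days = td, events = ev,
                 dominance = dom, daily = daily, behavior_means = means,
                 block_shares = blocks, replacement_days = repl_days,
                 comparisons = comp, truth = truth, manifest = manifest))
}

#' Rank-recovery simulation study
#'
#' For each despotism value and seed, simulates a small drinker-only herd,
#' detects replacements, runs the Elo stage, and scores how well the
#' estimated summed winning probabilities recover the latent dominance order
#' (Spearman's rho), together with the recovered steepness. This is the
#' package's internal validation study: recovery should improve with
#' interactions per animal, and steepness should increase with despotism.
#'
#' @param betas despotism values to simulate.
#' @param seeds integer seeds (one herd per beta x seed cell).
#' @param n_cows herd size (scalar, or vector recycled over seeds).
#' @param n_days simulated days.
#' @param visits_per_day drinker visits per cow per day (boosted above the
#'   full-herd default so small herds still accumulate contests).
#' @param threshold_s detection gap threshold.
#' @param r0,k,scale Elo parameters.
#' @return `data.frame` with one row per cell: `beta`, `seed`, `n_cows`,
#'   `n_events`, `interactions_per_animal`, `rho`, `steepness`,
#'   `precision`, `recall`.
#' @export
run_recovery_study <- function(betas = c(0, 2, 4, 8), seeds = 1:20,
                               n_cows = 16, n_days = 25, visits_per_day = 14,
                               threshold_s = 26,
                               r0 = 1000, k = 100, scale = 400) {
  n_cows <- rep_len(n_cows, length(seeds))
  rows <- list()
  for (b in betas) for (si in seq_along(seeds)) {
    nc <- n_cows[si]
    cfg <- herd_config(
      n_cows = nc, n_drinkers = max(1L, round(nc / 10)), n_feeders = 0,
      n_days = n_days, beta = b, drinker_visits_per_day = visits_per_day,
      feeder_visits_per_day = 0, hot_fraction = 0,
      turnover_interval_mean = n_days + 10,  # closed group: isolate recovery
      seed = seeds[si])
    sim <- simulate_herd(cfg)
    ev <- detect_replacements(sim$visits, threshold_s)
    st <- elo_run(ev, r0 = r0, k = k, scale = scale,
                  roster = sim$membership$animal_id)
    S <- summed_winning_prob(st)
    tr <- truth_report(sim$truth, ev, S)
    rows[[length(rows) + 1L]] <- data.frame(
      beta = b, seed = seeds[si], n_cows = nc, n_events = nrow(ev),
      interactions_per_animal = 2 * nrow(ev) / nc,
      rho = tr$rho_recovery, steepness = steepness(S),
      precision = tr$precision, recall = tr$recall)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
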