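#' Expected winning probability under the Elo model
#'
#' Base-10 logistic curve in the rating difference:
#' `p = 1 / (1 + 10^(-(r_i - r_j)/scale))`. Complementary
#' (`p(i,j) + p(j,i) = 1`) and strictly increasing in `r_i - r_j`.
#'
#' @param r_i,r_j ratings of the focal animal and its opponent (vectorised).
#' @param scale rating-difference scale of the curve (default 400, the
#'   chess convention: a 400-point edge wins with probability 10/11).
#' @return Probability in (0, 1).
#' @export
expected_win_prob <- function(r_i, r_j, scale = 400) {
  if (!is.numeric(scale) || any(scale <= 0)) stop("scale must be > 0", call. = FALSE)
  1 / (1 + 10^(-(r_i - r_j) / scale))
}

#' Create an Elo rating state
#'
#' @param animal_ids animals to enter at the prior rating immediately.
#' @param r0 prior rating given to every animal on first appearance.
#' @param k update step size (points transferred for a maximally unexpected
#'   outcome).
#' @param scale see [expected_win_prob()].
#' @return An object of class `elo_state` with named `ratings` and
#'   `n_interactions` vectors.
#' @export
elo_state <- function(animal_ids = character(0), r0 = 1000, k = 100, scale = 400) {
  stopifnot(k > 0, scale > 0)
  ids <- unique(as.character(animal_ids))
  structure(list(
    ratings = stats::setNames(rep(as.numeric(r0), length(ids)), ids),
    n_interactions = stats::setNames(integer(length(ids)), ids),
    r0 = r0, k = k, scale = scale, n_events = 0L), class = "elo_state")
}

#' @export
print.elo_state <- function(x, ...) {
  cat("Elo state:", length(x$ratings), "animals,", x$n_events, "events",
      sprintf("(r0=%g, k=%g, scale=%g)\n", x$r0, x$k, x$scale))
  invisible(x)
}

#' Apply one replacement outcome to an Elo state
#'
#' The actor (winner) gains `k * (1 - p)` points and the reactor (loser)
#' loses the same amount, where `p` is the actor's expected winning
#' probability before the interaction — expected outcomes move ratings
#' little, upsets move them a lot. Total rating mass is conserved. Animals
#' not yet rated are first entered at the prior `r0`, so newcomers join a
#' hierarchy whose accumulated history is retained.
#'
#' @param state an [elo_state()].
#' @param actor,reactor animal ids of winner and loser.
#' @return The updated `elo_state`.
#' @export
elo_update <- function(state, actor, reactor) {
  stopifnot(inherits(state, "elo_state"))
  actor <- as.character(actor); reactor <- as.character(reactor)
  if (actor == reactor) stop("invalid event: actor == reactor", call. = FALSE)
  for (id in c(actor, reactor)) if (!id %in% names(state$ratings)) {
    state$ratings[id] <- state$r0
    state$n_interactions[id] <- 0L
  }
  p <- expected_win_prob(state$ratings[[actor]], state$ratings[[reactor]],
                         state$scale)
  delta <- state$k * (1 - p)
  state$ratings[actor] <- state$ratings[[actor]] + delta
  state$ratings[reactor] <- state$ratings[[reactor]] - delta
  state$n_interactions[actor] <- state$n_interactions[[actor]] + 1L
  state$n_interactions[reactor] <- state$n_interactions[[reactor]] + 1L
  state$n_events <- state$n_events + 1L
  state
}

# tight inner loop shared by elo_run() and the resampling replicates:
# integer-indexed ratings, no name lookups
elo_core <- function(ai, bi, n_ids, r0, k, scale) {
  r <- rep(as.numeric(r0), n_ids)
  for (e in seq_along(ai)) {
    a <- ai[e]; b <- bi[e]
    p <- 1 / (1 + 10^((r[b] - r[a]) / scale))
    d <- k * (1 - p)
    r[a] <- r[a] + d
    r[b] <- r[b] - d
  }
  r
}

#' Run sequential Elo scoring over a time-ordered event sequence
#'
#' Processes replacement events in time order over a dynamic roster: animals
#' entering mid-sequence start at the prior `r0` while incumbents keep their
#' accumulated ratings, and animals that leave the group keep (frozen) their
#' last rating rather than being deleted — interaction history carries
#' through roster changes.
#'
#' @param events `data.frame` with `actor_id`, `reactor_id` and (optionally)
#'   `time`; if `time` is present it must be non-decreasing.
#' @param r0,k,scale Elo parameters, see [elo_state()].
#' @param roster optional character vector of animals to rate even if they
#'   never interact (entered at `r0`).
#' @return An `elo_state` after all events.
#' @export
elo_run <- function(events, r0 = 1000, k = 100, scale = 400, roster = NULL) {
  stopifnot(k > 0, scale > 0)
  if (!is.null(events$time) && is.unsorted(as.numeric(events$time)))
    stop("events must be sorted by time", call. = FALSE)
  if (any(events$actor_id == events$reactor_id))
    stop("invalid event: actor == reactor", call. = FALSE)
  ids <- unique(c(as.character(roster),
                  as.character(events$actor_id),
                  as.character(events$reactor_id)))
  st <- elo_state(ids, r0 = r0, k = k, scale = scale)
  if (nrow(events)) {
    ai <- match(events$actor_id, ids)
    bi <- match(events$reactor_id, ids)
    st$ratings[] <- elo_core(ai, bi, length(ids), r0, k, scale)
    tab_a <- tabulate(ai, length(ids)); tab_b <- tabulate(bi, length(ids))
    st$n_interactions[] <- tab_a + tab_b
    st$n_events <- nrow(events)
  }
  st
}

#' Summed winning probabilities (dominance scores)
#'
#' For each animal `i`, the expected winning probability against every other
#' animal in the opponent set, summed:
#' `S_i = sum_j p(r_i, r_j)`. With `n` animals, `S_i` ranges from 0 (loses to
#' everyone) to `n - 1` (beats everyone), and the scores always total
#' `n(n-1)/2` because each dyad's two probabilities sum to 1.
#'
#' @param state an `elo_state` (e.g. from [elo_run()]).
#' @param opponents animals forming the opponent set (default: all rated
#'   animals — "all potential opponents" over the whole observation window;
#'   pass a co-resident subset to restrict).
#' @return Named numeric vector `S`.
#' @export
summed_winning_prob <- function(state, opponents = NULL) {
  stopifnot(inherits(state, "elo_state"))
  opponents <- if (is.null(opponents)) names(state$ratings)
               else as.character(opponents)
  if (!all(opponents %in% names(state$ratings)))
    stop("opponents must all be rated animals", call. = FALSE)
  n <- length(opponents)
  if (n < 2L) stop("need at least 2 animals for summed winning probabilities",
                   call. = FALSE)
  r <- state$ratings[opponents]
  P <- 1 / (1 + 10^(outer(r, r, function(x, y) (y - x) / state$scale)))
  diag(P) <- 0
  rowSums(P)
}

#' Hierarchy steepness from dominance scores
#'
#' Sorts the summed winning probabilities in descending order, regresses them
#' on rank 1..n by ordinary least squares, and returns the absolute slope,
#' clipped into \[0, 1\]. 0 means an egalitarian group (all scores equal);
#' 1 a maximally despotic linear ladder where adjacent ranks differ by a full
#' expected win. Ties in the sort are broken by animal name so the result is
#' deterministic.
#'
#' @param S named (or unnamed) numeric vector of summed winning probabilities.
#' @return Steepness in \[0, 1\].
#' @export
steepness <- function(S) {
  n <- length(S)
  if (n < 2L) stop("steepness needs at least 2 animals", call. = FALSE)
  nm <- names(S) %||% as.character(seq_len(n))
  y <- S[order(-S, nm)]
  x <- seq_len(n)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  min(1, abs(slope))
}

#' Dominance summary with resampling-based uncertainty
#'
#' Computes point estimates of per-animal summed winning probabilities and
#' hierarchy steepness from the observed event order, then quantifies their
#' sensitivity by rerunning the Elo sequence over `n_rep` replicates in which
#' the event order is randomly permuted (`mode = "shuffle"`; Elo results
#' depend on sequence order, so this isolates ordering uncertainty) or the
#' events are resampled with replacement (`mode = "bootstrap"`; sampling
#' uncertainty). Replicate means and SDs are reported per animal and for
#' steepness.
#'
#' This is a deliberately lightweight, simulation-based stand-in for Bayesian
#' posterior machinery: the SD bands have the same role but are not posterior
#' SDs.
#'
#' @param events time-sorted replacement events.
#' @param n_rep number of replicates (>= 2; default 1000).
#' @param mode `"shuffle"` or `"bootstrap"`.
#' @param seed optional integer seed.
#' @param r0,k,scale Elo parameters.
#' @param roster,opponents optional roster to rate and opponent set for `S`
#'   (defaults: animals appearing in `events`).
#' @return Object of class `dominance_summary`: `$animals` is a `data.frame`
#'   with `animal_id`, `S` (point), `S_mean`, `S_sd`, `n_interactions`,
#'   `rank` (1 = highest `S_mean`); `$steepness` is a list with `point`,
#'   `mean`, `sd`, `n_rep`, `mode`, `seed`.
#' @export
elo_summary <- function(events, n_rep = 1000, mode = c("shuffle", "bootstrap"),
                        seed = NULL, r0 = 1000, k = 100, scale = 400,
                        roster = NULL, opponents = NULL) {
  mode <- match.arg(mode)
  if (n_rep < 2) stop("n_rep must be >= 2", call. = FALSE)
  if (!is.null(events$time) && is.unsorted(as.numeric(events$time)))
    stop("events must be sorted by time", call. = FALSE)
  if (nrow(events) < 1L) stop("no events to summarise", call. = FALSE)
  if (any(events$actor_id == events$reactor_id))
    stop("invalid event: actor == reactor", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ids <- unique(c(as.character(roster), events$actor_id, events$reactor_id))
  ai <- match(events$actor_id, ids)
  bi <- match(events$reactor_id, ids)
  n_ids <- length(ids)
  opp <- if (is.null(opponents)) ids else as.character(opponents)
  oi <- match(opp, ids)
  if (anyNA(oi)) stop("opponents must appear in events or roster", call. = FALSE)
  if (length(oi) < 2L) stop("need >= 2 animals", call. = FALSE)

  S_of <- function(r) {
    ro <- r[oi]
    P <- 1 / (1 + 10^(outer(ro, ro, function(x, y) (y - x) / scale)))
    diag(P) <- 0
    rowSums(P)
  }
  r_point <- elo_core(ai, bi, n_ids, r0, k, scale)
  S_point <- S_of(r_point)
  steep_point <- steepness(stats::setNames(S_point, opp))

  m <- length(ai)
  S_mat <- matrix(NA_real_, nrow = length(oi), ncol = n_rep)
  steep_rep <- numeric(n_rep)
  for (rep_i in seq_len(n_rep)) {
    idx <- if (mode == "shuffle") sample.int(m) else sample.int(m, replace = TRUE)
    r <- elo_core(ai[idx], bi[idx], n_ids, r0, k, scale)
    S <- S_of(r)
    S_mat[, rep_i] <- S
    steep_rep[rep_i] <- steepness(stats::setNames(S, opp))
  }
  S_mean <- rowMeans(S_mat)
  S_sd <- apply(S_mat, 1, stats::sd)
  n_int <- tabulate(ai, n_ids) + tabulate(bi, n_ids)
  animals <- data.frame(
    animal_id = opp, S = unname(S_point), S_mean = S_mean, S_sd = S_sd,
    n_interactions = n_int[oi], stringsAsFactors = FALSE)
  animals$rank <- rank_by_desc(animals$S_mean, animals$animal_id)
  animals <- animals[order(animals$rank), , drop = FALSE]
  rownames(animals) <- NULL
  structure(list(
    animals = animals,
    steepness = list(point = steep_point, mean = mean(steep_rep),
                     sd = stats::sd(steep_rep), n_rep = n_rep, mode = mode,
                     seed = seed),
    params = list(r0 = r0, k = k, scale = scale),
    n_events = m), class = "dominance_summary")
}

rank_by_desc <- function(x, nm) {
  ord <- order(-x, nm)
  r <- integer(length(x)); r[ord] <- seq_along(x)
  r
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf(
    "Dominance summary: %d animals, %d events\n  steepness %.3f (resampling mean %.3f, sd %.3f, %d x %s)\n",
    nrow(x$animals), x$n_events, x$steepness$point, x$steepness$mean,
    x$steepness$sd, x$steepness$n_rep, x$steepness$mode))
  top <- utils::head(x$animals, 5L)
  cat("  top ranks:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %2d. %s  S = %.2f +/- %.2f (%d interactions)\n",
                top$rank[i], top$animal_id[i], top$S_mean[i], top$S_sd[i],
                top$n_interactions[i]))
  invisible(x)
}
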