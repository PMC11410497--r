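#' Detect agonistic replacement events from a visit log
#'
#' A replacement is one animal displacing another from a bin and occupying
#' its spot within a short time: operationally, visit `v2` immediately
#' follows visit `v1` at the same bin, the animals differ, and the
#' exit-to-entry gap `v2$start - v1$end` lies in `[0, threshold_s]`. The
#' later arriver is the actor (winner), the displaced animal the reactor
#' (loser). Only the immediately next visit at a bin can form an event with a
#' given exit, and no cross-bin displacement is inferred.
#'
#' The gap threshold is a tunable of the detection hardware/algorithm, not a
#' biological constant; 26 s is a conventional short-gap default for
#' electronic feed/water bins.
#'
#' @param v validated visit table (non-overlapping per bin).
#' @param threshold_s maximum exit-to-entry gap in seconds (default 26).
#' @return `data.frame` with columns `actor_id`, `reactor_id`, `bin_id`,
#'   `bin_type`, `time` (the actor's entry, `POSIXct`), `gap_s`, sorted by
#'   `time`.
#' @export
detect_replacements <- function(v, threshold_s = 26) {
  if (!is.numeric(threshold_s) || length(threshold_s) != 1L || threshold_s < 0)
    stop("threshold_s must be a single non-negative number", call. = FALSE)
  v <- canonical_visit_order(v)
  n <- nrow(v)
  empty <- data.frame(actor_id = character(0), reactor_id = character(0),
                      bin_id = character(0), bin_type = character(0),
                      time = as.POSIXct(character(0), tz = "UTC"),
                      gap_s = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  gap <- as.numeric(v$start[i2]) - as.numeric(v$end[i1])
  hit <- v$bin_id[i1] == v$bin_id[i2] &
    v$animal_id[i1] != v$animal_id[i2] &
    gap >= 0 & gap <= threshold_s
  if (!any(hit)) return(empty)
  w <- which(hit)
  ev <- data.frame(actor_id = v$animal_id[w + 1L],
                   reactor_id = v$animal_id[w],
                   bin_id = v$bin_id[w],
                   bin_type = v$bin_type[w],
                   time = v$start[w + 1L],
                   gap_s = gap[w], stringsAsFactors = FALSE)
  ev <- ev[order(ev$time, ev$bin_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Largest-remainder apportionment
#'
#' Distributes `n_target` units over categories proportionally to `counts`
#' (Hamilton's method): each category gets the floor of its exact quota, and
#' leftover units go to the largest fractional remainders, ties broken by
#' category name for determinism.
#'
#' @param counts named non-negative integer vector.
#' @param n_target total to apportion, `0 <= n_target <= sum(counts)`.
#' @return Named integer vector summing to `n_target`, each entry at most the
#'   original count.
#' @export
apportion_largest_remainder <- function(counts, n_target) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (n_target < 0 || n_target > sum(counts))
    stop("n_target must be between 0 and sum(counts)", call. = FALSE)
  quota <- n_target * counts / sum(counts)
  base <- floor(quota + 1e-9)  # guard exact quotas against fp round-down
  rem <- n_target - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, names(counts))
    add <- ord[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  # apportionment can never exceed the available count since quota <= counts
  storage.mode(base) <- "integer"
  base
}

#' Actor-proportional subsample of replacement events
#'
#' Draws `n_target` events keeping each actor's share of events as close as
#' possible to its share in the full set (largest-remainder apportionment of
#' the per-actor counts), then samples uniformly without replacement within
#' each actor. Used to put hierarchies from unequally sampled resources
#' (e.g. 30 feeders vs 5 drinkers) on a comparable data footing.
#'
#' @param events replacement event table from [detect_replacements()].
#' @param n_target number of events to keep.
#' @param seed optional integer seed for reproducibility.
#' @return Subsampled events, time-sorted.
#' @export
subsample_proportional <- function(events, n_target, seed = NULL) {
  if (n_target > nrow(events) || n_target < 0)
    stop("n_target must be between 0 and the number of events", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n_target == nrow(events)) return(events)
  counts <- table(events$actor_id)
  alloc <- apportion_largest_remainder(
    stats::setNames(as.integer(counts), names(counts)), n_target)
  keep <- integer(0)
  for (a in names(alloc)) {
    if (alloc[[a]] == 0L) next
    idx <- which(events$actor_id == a)
    keep <- c(keep, if (length(idx) == alloc[[a]]) idx
              else idx[sample.int(length(idx), alloc[[a]])])
  }
  out <- events[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
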