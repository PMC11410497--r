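# Independent brute-force oracles and programmatic fixtures used across the
# suite. Oracles deliberately avoid sharing code paths with the package.

base_ts <- as.POSIXct("2020-07-01 00:00:00", tz = "UTC")

mk_visits <- function(animal, bin, start_s, end_s, type = "drinker",
                      intake = 1) {
  data.frame(animal_id = animal, bin_id = bin, bin_type = type,
             start = base_ts + start_s, end = base_ts + end_s,
             intake_kg = intake, stringsAsFactors = FALSE)
}

# visits laid end-to-end per bin with random gaps straddling the threshold
random_visit_log <- function(n = 200, n_bins = 4, n_cows = 8, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n)
  per_bin <- ceiling(n / n_bins)
  k <- 0
  for (b in seq_len(n_bins)) {
    t <- sample(0:500, 1)
    for (i in seq_len(per_bin)) {
      if (k >= n) break
      k <- k + 1
      gap <- sample(0:60, 1)
      dur <- sample(20:300, 1)
      rows[[k]] <- mk_visits(sprintf("c%02d", sample(n_cows, 1)),
                             sprintf("B%d", b), t + gap, t + gap + dur,
                             intake = round(runif(1, 0, 15), 3))
      t <- t + gap + dur
    }
  }
  validate_visits(do.call(rbind, rows))
}

# O(n^2) adjacency scan: (i, j) is a replacement iff same bin, j starts at
# or after i ends within the threshold, no visit at that bin starts between
# them, and the animals differ
oracle_detect <- function(v, threshold) {
  n <- nrow(v)
  hits <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || v$bin_id[i] != v$bin_id[j]) next
    gap <- as.numeric(v$start[j]) - as.numeric(v$end[i])
    if (gap < 0 || gap > threshold) next
    between <- any(v$bin_id == v$bin_id[i] &
                     as.numeric(v$start) > as.numeric(v$start[i]) &
                     as.numeric(v$start) < as.numeric(v$start[j]))
    if (between) next
    if (v$animal_id[i] == v$animal_id[j]) next
    hits[[length(hits) + 1]] <- data.frame(
      actor_id = v$animal_id[j], reactor_id = v$animal_id[i],
      bin_id = v$bin_id[i], time = v$start[j], gap_s = gap,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(out)
  out[order(out$time, out$bin_id), , drop = FALSE]
}

# double-loop summed winning probability
oracle_S <- function(ratings, scale) {
  n <- length(ratings)
  S <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    S[i] <- S[i] + 1 / (1 + 10^(-(ratings[i] - ratings[j]) / scale))
  names(S) <- names(ratings)
  S
}

random_events <- function(n = 50, n_cows = 6, seed = 1) {
  set.seed(seed)
  pairs <- t(replicate(n, sample(n_cows, 2)))
  data.frame(actor_id = sprintf("c%d", pairs[, 1]),
             reactor_id = sprintf("c%d", pairs[, 2]),
             time = base_ts + seq_len(n) * 60, stringsAsFactors = FALSE)
}
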