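#' Spearman rank correlation with tie-aware midranks
#'
#' `rho` is the Pearson correlation of the midranks (average ranks for ties).
#' The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (adequate for the n of 40-90 this pipeline targets); for `n <= 8` an
#' exact permutation p-value over all `n!` orderings is available.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param method `"t-approx"` (default) or `"exact"` (permutation; `n <= 8`).
#' @return List with `rho`, `p`, `n`, `method`. Zero variance in either
#'   vector yields `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y, method = c("t-approx", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = method))
  }
  rho <- stats::cor(rx, ry)
  if (method == "t-approx") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    if (n > 8) stop("exact permutation p limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Welch's unequal-variances t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value from Student's t. Taking
#' summary statistics (rather than raw vectors) makes published group
#' summaries directly checkable.
#'
#' @param mean1,sd1,n1 first group summary (`n1 >= 2`, `sd1 > 0`).
#' @param mean2,sd2,n2 second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  list(t = tt, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, sets `p_adj(i) = min_{j >= i} min(1, p(j)*m/j)`,
#' and restores the original order. Output is invariant to input permutation
#' and monotone non-decreasing along the sorted order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  padj_sorted <- pmin(1, p[ord] * m / seq_len(m))
  padj_sorted <- rev(cummin(rev(padj_sorted)))
  out <- numeric(m)
  out[ord] <- padj_sorted
  out
}

get_S <- function(x) {
  if (inherits(x, "dominance_summary"))
    return(stats::setNames(x$animals$S_mean, x$animals$animal_id))
  if (is.data.frame(x)) {
    col <- if ("S_mean" %in% names(x)) "S_mean" else "S"
    return(stats::setNames(x[[col]], x$animal_id))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot extract dominance scores", call. = FALSE)
}

#' Assemble the dominance-behaviour comparison tables
#'
#' Produces the study-level statistical comparisons from upstream module
#' outputs:
#' \itemize{
#'   \item `feeder_vs_drinker`: Spearman correlation of summed winning
#'     probabilities over animals present in both hierarchies;
#'   \item `hot_vs_normal`: the same for the two heat-period hierarchies;
#'   \item per period, correlations of dominance with average daily visit
#'     count, drinking duration and water intake (unadjusted by default;
#'     set `adjust_daily = TRUE` to BH-adjust within each period);
#'   \item per period and metric, correlations of dominance with each
#'     diurnal block share, BH-adjusted within each (metric, period) family
#'     of `n_blocks` tests;
#'   \item Welch's t-test on daily group replacement counts, hot vs normal.
#' }
#'
#' @param dominance named list of dominance summaries (or named `S` vectors);
#'   recognised names: `drinker`, `feeder`, `hot`, `normal`. Period-specific
#'   behaviour correlations use the matching period hierarchy when present,
#'   else `drinker`.
#' @param behavior output of [behavior_means()] (may be `NULL` to skip).
#' @param blocks output of [block_shares()] (may be `NULL` to skip).
#' @param replacement_days `data.frame` with `date`, `period`, `n_events`
#'   of daily drinker replacement counts (may be `NULL` to skip the Welch
#'   comparison).
#' @param adjust_daily BH-adjust the daily-metric family too (default FALSE).
#' @return List with `correlations` (tidy `data.frame`: `family`, `label`,
#'   `rho`, `p`, `p_adj`, `n`) and `welch` (one-row `data.frame` or `NULL`).
#' @export
assemble_comparisons <- function(dominance, behavior = NULL, blocks = NULL,
                                 replacement_days = NULL,
                                 adjust_daily = FALSE) {
  rows <- list()
  add <- function(family, label, sp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, label = label, rho = sp$rho, p = sp$p,
      p_adj = NA_real_, n = sp$n, stringsAsFactors = FALSE)
  }
  cor_pair <- function(a, b, family, label) {
    Sa <- get_S(dominance[[a]]); Sb <- get_S(dominance[[b]])
    shared <- intersect(names(Sa), names(Sb))
    if (length(shared) == 0L)
      stop("no shared animals between ", a, " and ", b, call. = FALSE)
    add(family, label, spearman_cor(Sa[shared], Sb[shared]))
  }
  if (all(c("feeder", "drinker") %in% names(dominance)))
    cor_pair("feeder", "drinker", "hierarchy", "feeder_vs_drinker")
  if (all(c("hot", "normal") %in% names(dominance)))
    cor_pair("hot", "normal", "hierarchy", "hot_vs_normal")

  S_for_period <- function(per) {
    src <- if (per %in% names(dominance)) per else "drinker"
    get_S(dominance[[src]])
  }
  if (!is.null(behavior)) {
    for (per in sort(unique(behavior$period))) {
      S <- S_for_period(per)
      bb <- behavior[behavior$period == per, , drop = FALSE]
      shared <- intersect(names(S), bb$animal_id)
      bb <- bb[match(shared, bb$animal_id), , drop = FALSE]
      for (metric in c("mean_visits", "mean_duration_s", "mean_intake_kg"))
        add(paste0("daily_", per), paste0(metric, "_", per),
            spearman_cor(S[shared], bb[[metric]]))
    }
  }
  if (!is.null(blocks)) {
    for (per in sort(unique(blocks$period))) {
      S <- S_for_period(per)
      for (metric in c("pct_visits", "pct_duration", "pct_intake")) {
        for (b in sort(unique(blocks$block))) {
          bb <- blocks[blocks$period == per & blocks$block == b, , drop = FALSE]
          shared <- intersect(names(S), bb$animal_id[!is.na(bb[[metric]])])
          bb <- bb[match(shared, bb$animal_id), , drop = FALSE]
          add(paste0("blocks_", metric, "_", per),
              sprintf("%s_block%d_%s", metric, b, per),
              spearman_cor(S[shared], bb[[metric]]))
        }
      }
    }
  }
  correlations <- do.call(rbind, rows)
  if (!is.null(correlations)) {
    for (fam in unique(correlations$family)) {
      i <- correlations$family == fam
      adjust <- startsWith(fam, "blocks_") ||
        (adjust_daily && startsWith(fam, "daily_"))
      correlations$p_adj[i] <- if (adjust) bh_adjust(correlations$p[i])
                               else correlations$p[i]
    }
  }
  welch <- NULL
  if (!is.null(replacement_days)) {
    hot <- replacement_days$n_events[replacement_days$period == "hot"]
    nor <- replacement_days$n_events[replacement_days$period == "normal"]
    if (length(hot) >= 2 && length(nor) >= 2 &&
        stats::sd(hot) > 0 && stats::sd(nor) > 0) {
      w <- welch_t(mean(hot), stats::sd(hot), length(hot),
                   mean(nor), stats::sd(nor), length(nor))
      welch <- data.frame(
        comparison = "replacements_per_day_hot_vs_normal",
        mean_hot = mean(hot), sd_hot = stats::sd(hot), n_hot = length(hot),
        mean_normal = mean(nor), sd_normal = stats::sd(nor),
        n_normal = length(nor), t = w$t, df = w$df, p = w$p,
        stringsAsFactors = FALSE)
    }
  }
  list(correlations = correlations, welch = welch)
}
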