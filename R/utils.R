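`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric x as 1:x; this never does
sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

visit_date <- function(ts) as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

canonical_visit_order <- function(v) v[order(v$bin_id, v$start), , drop = FALSE]
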