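# Independent oracles and small fixture builders used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a run_counts object from a counts matrix and a (sample, group) layout
make_runs <- function(counts, samples, groups) {
  manifest <- data.frame(run_id = colnames(counts),
                         sample_id = samples, group = groups,
                         stringsAsFactors = FALSE)
  run_counts(counts, manifest)
}

# brute-force integer scan of the CI lower bound: smallest m with
# m - t * sqrt(pv / n) > 0
brute_threshold <- function(pooled_variance, df, n, confidence = 0.95) {
  tq <- qt((1 + confidence) / 2, df)
  m <- 1L
  while (!(m - tq * sqrt(pooled_variance / n) > 0)) m <- m + 1L
  m
}

# closed-form pooled-SD two-sample t, written from the textbook formula
brute_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  t <- (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# exhaustive-enumeration upper-tail hypergeometric: draw n from a universe
# of size N containing a K-sized set; P(overlap >= k) counted over all
# C(N, n) draws
enum_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # the set occupies labels 1..K
  mean(hits >= k)
}

# closed-form paired one-tailed t
brute_paired_p <- function(control, treated, lower = TRUE) {
  d <- treated - control
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  pt(t, length(d) - 1, lower.tail = lower)
}

# small two-group matrix fixture from explicit replicate values
make_matrix <- function(values, groups) {
  structure(list(values = values, groups = groups,
                 factors = setNames(numeric(0), character(0))),
            class = "count_matrix")
}
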