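#' Fold change between two group means
#'
#' Ratio of the larger mean to the smaller. With one mean zero the fold is
#' +Inf (an on/off transcript passes any finite fold filter); with both
#' means zero the fold is undefined (NA).
#'
#' @param mean_a,mean_b non-negative group means (vectorized).
#' @return Numeric vector of folds >= 1 (or Inf / NA).
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE)) {
    stop_validation("group means must be non-negative")
  }
  hi <- pmax(mean_a, mean_b)
  lo <- pmin(mean_a, mean_b)
  ifelse(hi == 0, NA_real_, hi / lo)  # lo == 0, hi > 0 gives Inf
}

#' Three-filter differential transcript test
#'
#' The calling procedure applied to the normalized, run-summed count matrix:
#' a transcript is called differential when (i) its larger group mean
#' reaches the detection threshold, (ii) a two-sided pooled-variance
#' (classic Student's) two-sample t-test on the biological-replicate values
#' gives p <= alpha, and (iii) the fold change between group means is at
#' least `min_fold`. All transcripts are returned with their three flags so
#' the filter funnel is auditable; no multiple-testing correction is
#' applied, matching the procedure this package implements.
#'
#' When the pooled variance is zero for a transcript (both groups constant)
#' the t statistic is undefined: p is NA, `passes_p` is FALSE.
#'
#' @param matrix a `count_matrix` with exactly two groups, >= 2 biological
#'   samples each.
#' @param alpha p-value cutoff (default 0.1).
#' @param min_fold minimum fold change (default 2).
#' @param min_reads a `detection_threshold` or a single number.
#' @param threshold_rule how the read filter is applied: `"either"`
#'   (default; the larger group mean must reach the threshold), `"both"`,
#'   or `"mean"` (overall mean across all samples).
#' @return Data frame of class `de_result`, one row per transcript:
#'   transcript_id, mean_a, mean_b, fold_change, direction (which group is
#'   higher), p_value, passes_threshold, passes_p, passes_fold, called.
#'   Group labels are stored in attributes `group_a` / `group_b` and the
#'   parameters in attribute `params`.
#' @export
differential_test <- function(matrix, alpha = 0.1, min_fold = 2.0,
                              min_reads,
                              threshold_rule = c("either", "both", "mean")) {
  stopifnot(inherits(matrix, "count_matrix"))
  threshold_rule <- match.arg(threshold_rule)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(min_fold, "min_fold", lower = 1)
  thr <- if (inherits(min_reads, "detection_threshold")) min_reads$threshold
         else check_number(min_reads, "min_reads", lower = 0)
  groups <- unique(matrix$groups)
  if (length(groups) != 2L) {
    stop_validation("exactly two groups required, got ", length(groups))
  }
  xa <- matrix$values[, matrix$groups == groups[1], drop = FALSE]
  xb <- matrix$values[, matrix$groups == groups[2], drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2L || nb < 2L) {
    stop_validation("each group needs >= 2 biological replicates")
  }
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2L)

  fc <- fold_change(ma, mb)
  direction <- ifelse(ma > mb, groups[1],
                      ifelse(mb > ma, groups[2], NA_character_))
  passes_threshold <- switch(threshold_rule,
    either = pmax(ma, mb) >= thr,
    both = pmin(ma, mb) >= thr,
    mean = rowMeans(matrix$values) >= thr
  )
  passes_p <- !is.na(p) & p <= alpha
  passes_fold <- !is.na(fc) & fc >= min_fold
  res <- data.frame(
    transcript_id = rownames(matrix$values),
    mean_a = ma, mean_b = mb,
    fold_change = fc, direction = direction, p_value = p,
    passes_threshold = passes_threshold, passes_p = passes_p,
    passes_fold = passes_fold,
    called = passes_threshold & passes_p & passes_fold,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "group_a") <- groups[1]
  attr(res, "group_b") <- groups[2]
  attr(res, "params") <- list(alpha = alpha, min_fold = min_fold,
                              min_reads = thr,
                              threshold_rule = threshold_rule)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Summarize differential calls and the filter funnel
#'
#' @param results a `de_result` from [differential_test()].
#' @return List: `n_tested`, `n_called`, `by_direction` (named call counts),
#'   `n_fail_threshold`, `n_fail_p`, `n_fail_fold` (each filter evaluated
#'   independently over all tested transcripts).
#' @export
summarize_calls <- function(results) {
  dirs <- c(attr(results, "group_a"), attr(results, "group_b"))
  by_dir <- if (nrow(results) == 0) stats::setNames(c(0L, 0L), dirs) else
    vapply(dirs, function(d) {
      sum(results$called & !is.na(results$direction) &
            results$direction == d)
    }, integer(1))
  list(
    n_tested = nrow(results),
    n_called = sum(results$called),
    by_direction = by_dir,
    n_fail_threshold = sum(!results$passes_threshold),
    n_fail_p = sum(!results$passes_p),
    n_fail_fold = sum(!results$passes_fold)
  )
}
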