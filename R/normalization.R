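#' Run-level count container
#'
#' Bundles an integer count matrix (transcripts x sequencing runs) with the
#' run manifest mapping each run to its biological sample and treatment
#' group. Totals are computed from the counts, never trusted from file.
#'
#' @param counts integer matrix, rownames = transcript ids, colnames =
#'   run ids.
#' @param manifest data frame with columns run_id, sample_id, group.
#' @return Object of class `run_counts` with elements `counts`, `manifest`,
#'   `totals` (named per-run totals of alignable reads).
#' @export
run_counts <- function(counts, manifest) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop_validation("'counts' must be a matrix with transcript rownames ",
                    "and run colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_validation("transcript ids must be unique")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation("counts must be non-negative integers; first offence ",
                    "at transcript '", rownames(counts)[bad[1, 1]],
                    "', run '", colnames(counts)[bad[1, 2]], "'")
  }
  req <- c("run_id", "sample_id", "group")
  if (!all(req %in% names(manifest))) {
    stop_validation("manifest needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(manifest$run_id)) {
    stop_validation("duplicate run_id in manifest")
  }
  missing_col <- setdiff(manifest$run_id, colnames(counts))
  if (length(missing_col)) {
    stop_validation("manifest run(s) absent from count columns: ",
                    paste(missing_col, collapse = ", "))
  }
  if (anyDuplicated(unique(manifest[, c("sample_id", "group")])$sample_id)) {
    stop_validation("a sample maps to more than one group")
  }
  counts <- counts[, manifest$run_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 manifest = as.data.frame(manifest)[, req],
                 totals = colSums(counts)),
            class = "run_counts")
}

#' @export
print.run_counts <- function(x, ...) {
  cat("run_counts:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "runs;", length(unique(x$manifest$sample_id)), "samples in",
      length(unique(x$manifest$group)), "groups\n")
  invisible(x)
}

#' Library-size normalization factors
#'
#' The run with the smallest total of alignable reads anchors the scale:
#' every run's factor is min(total) / total, so multiplying a run's counts
#' by its factor brings all run totals down to the common minimum.
#'
#' @param run_totals named numeric vector of per-run total alignable reads,
#'   or a `run_counts` object.
#' @return Named numeric vector of factors in (0, 1]; the minimum-total run
#'   gets exactly 1.
#' @export
compute_normalization_factors <- function(run_totals) {
  if (inherits(run_totals, "run_counts")) run_totals <- run_totals$totals
  if (length(run_totals) == 0L) {
    stop_validation("no runs supplied")
  }
  if (anyNA(run_totals) || any(run_totals <= 0)) {
    empty <- names(run_totals)[which(is.na(run_totals) | run_totals <= 0)]
    stop_validation("run(s) with no alignable reads: ",
                    paste(empty, collapse = ", "))
  }
  min(run_totals) / run_totals
}

#' Normalize runs and sum technical runs per biological replicate
#'
#' Multiplies each run's counts by its normalization factor, then sums the
#' runs belonging to each biological sample, yielding one normalized value
#' per transcript per biological replicate. Normalized values stay real
#' (no re-rounding), which preserves mass exactly.
#'
#' @param runs a `run_counts` object.
#' @param factors named factors from [compute_normalization_factors()];
#'   computed from `runs` when `NULL`.
#' @return Object of class `count_matrix`: `values` (transcripts x samples),
#'   `groups` (named by sample), `factors` used.
#' @export
normalize_and_sum <- function(runs, factors = NULL) {
  stopifnot(inherits(runs, "run_counts"))
  if (is.null(factors)) factors <- compute_normalization_factors(runs)
  man <- runs$manifest
  missing_f <- setdiff(man$run_id, names(factors))
  if (length(missing_f)) {
    stop_validation("no factor for run(s): ", paste(missing_f, collapse = ", "))
  }
  runs_per_sample <- table(man$sample_id)
  if (length(unique(runs_per_sample)) != 1L) {
    stop_validation("all biological samples must have the same number of runs")
  }
  norm <- sweep(runs$counts, 2L, factors[man$run_id], `*`)
  samples <- unique(man$sample_id)
  values <- vapply(samples, function(s) {
    rowSums(norm[, man$run_id[man$sample_id == s], drop = FALSE])
  }, numeric(nrow(norm)))
  if (!is.matrix(values)) values <- matrix(values, ncol = length(samples))
  dimnames(values) <- list(rownames(runs$counts), samples)
  groups <- man$group[match(samples, man$sample_id)]
  names(groups) <- samples
  structure(list(values = values, groups = groups,
                 factors = factors[man$run_id]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "transcripts x", ncol(x$values),
      "samples (groups:",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Detection threshold from an ingredient set
#'
#' Smallest positive integer mean m whose one-sample confidence interval,
#' built from the pooled between-run variance, excludes zero:
#' m - t_{(1+conf)/2, df} * sqrt(pooled_variance / n) > 0.
#'
#' @param pooled_variance pooled between-run variance of normalized counts.
#' @param df degrees of freedom for the t quantile.
#' @param n biological replicates per group entering the mean.
#' @param confidence confidence level of the interval.
#' @return Integer threshold (>= 1).
#' @export
threshold_from_ingredients <- function(pooled_variance, df, n,
                                       confidence = 0.95) {
  check_number(pooled_variance, "pooled_variance", lower = 0)
  check_number(df, "df", lower = 1)
  check_number(n, "n", lower = 1)
  check_number(confidence, "confidence", lower = 0, upper = 1)
  half <- stats::qt((1 + confidence) / 2, df) * sqrt(pooled_variance / n)
  as.integer(floor(half)) + 1L
}

#' Detection threshold from technical-run variability
#'
#' Estimates the between-run technical variance of normalized counts, pooled
#' over all run pairs and averaged over transcripts with any reads, and
#' returns the smallest integer mean read count statistically greater than
#' zero at the given confidence. Transcripts with zero counts in every run
#' carry no technical-noise information and are excluded from the pooling.
#'
#' @param runs a `run_counts` object (>= 2 runs per biological sample).
#' @param factors normalization factors; computed from `runs` when `NULL`.
#' @param confidence confidence level (default 0.95).
#' @return Object of class `detection_threshold`: `threshold`, `confidence`,
#'   `pooled_variance`, `df`, `n` (replicates per group), `half_width`.
#' @export
detection_threshold <- function(runs, factors = NULL, confidence = 0.95) {
  stopifnot(inherits(runs, "run_counts"))
  check_number(confidence, "confidence", lower = 0, upper = 1)
  if (is.null(factors)) factors <- compute_normalization_factors(runs)
  man <- runs$manifest
  runs_per_sample <- table(man$sample_id)
  if (any(runs_per_sample < 2L)) {
    stop_validation("between-run variance is inestimable: sample(s) with a ",
                    "single run: ",
                    paste(names(runs_per_sample)[runs_per_sample < 2L],
                          collapse = ", "))
  }
  norm <- sweep(runs$counts, 2L, factors[man$run_id], `*`)
  keep <- rowSums(norm) > 0
  if (!any(keep)) {
    stop_validation("no transcript with nonzero counts")
  }
  samples <- unique(man$sample_id)
  # per-transcript variance across the technical runs of each sample
  vars <- vapply(samples, function(s) {
    m <- norm[keep, man$run_id[man$sample_id == s], drop = FALSE]
    rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
  }, numeric(sum(keep)))
  if (!is.matrix(vars)) vars <- matrix(vars, nrow = 1L)
  pooled_variance <- mean(rowMeans(vars))
  df <- length(samples) - 1L
  groups <- man$group[match(samples, man$sample_id)]
  n <- min(table(groups))
  half <- stats::qt((1 + confidence) / 2, df) * sqrt(pooled_variance / n)
  structure(list(
    threshold = threshold_from_ingredients(pooled_variance, df, n, confidence),
    confidence = confidence, pooled_variance = pooled_variance,
    df = df, n = n, half_width = half
  ), class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf(paste0("detection threshold: %d reads (%.0f%% CI half-width ",
                     "%.3f; pooled variance %.4f, df %d, n %d)\n"),
              x$threshold, 100 * x$confidence, x$half_width,
              x$pooled_variance, x$df, x$n))
  invisible(x)
}

#' Check a contamination-marker transcript against the detection threshold
#'
#' The experiment's purity check: a transcript highly abundant in the
#' surrounding somatic cells (aromatase, CYP19A1, for cumulus cells) must
#' stay below the detection threshold in every group, otherwise the oocyte
#' pools are suspect.
#'
#' @param matrix a `count_matrix`.
#' @param marker_id marker transcript id (must be present; absence is an
#'   error, never a silent pass).
#' @param threshold a `detection_threshold` or a single number.
#' @return List of class `contamination_verdict`: `marker_id`, `group_means`,
#'   `threshold`, `pass`.
#' @export
contamination_check <- function(matrix, marker_id, threshold) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!marker_id %in% rownames(matrix$values)) {
    stop_validation("marker transcript '", marker_id,
                    "' absent from the count matrix")
  }
  thr <- if (inherits(threshold, "detection_threshold")) threshold$threshold
         else check_number(threshold, "threshold", lower = 0)
  gm <- tapply(matrix$values[marker_id, ], matrix$groups, mean)
  group_means <- stats::setNames(as.vector(gm), dimnames(gm)[[1]])
  structure(list(marker_id = marker_id,
                 group_means = group_means,
                 threshold = thr,
                 pass = all(group_means < thr)),
            class = "contamination_verdict")
}

#' @export
print.contamination_verdict <- function(x, ...) {
  cat("contamination check for", x$marker_id, "-",
      if (x$pass) "PASS" else "FAIL", "\n")
  for (g in names(x$group_means)) {
    cat(sprintf("  mean normalized reads in %s: %.2f (threshold %s)\n",
                g, x$group_means[[g]], format(x$threshold)))
  }
  invisible(x)
}
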