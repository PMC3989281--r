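#' Validate an oocyte outcome table
#'
#' Checks stage monotonicity within each row (blastocysts <= cleaved <=
#' metaphase II <= cultured) and non-negative counts.
#'
#' @param outcomes data frame: treatment, replicate, n_cultured, n_mii,
#'   n_cleaved, n_blastocyst.
#' @return The table, invisibly, with class `outcome_table`.
#' @export
validate_outcomes <- function(outcomes) {
  req <- c("treatment", "replicate", "n_cultured", "n_mii", "n_cleaved",
           "n_blastocyst")
  if (!all(req %in% names(outcomes))) {
    stop_validation("outcome table needs columns ",
                    paste(req, collapse = ", "))
  }
  cnt <- outcomes[, c("n_cultured", "n_mii", "n_cleaved", "n_blastocyst")]
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_validation("stage counts must be non-negative integers")
  }
  bad <- outcomes$n_blastocyst > outcomes$n_cleaved |
    outcomes$n_cleaved > outcomes$n_mii |
    outcomes$n_mii > outcomes$n_cultured
  if (any(bad)) {
    stop_validation("stage counts must be non-increasing along cultured -> ",
                    "MII -> cleaved -> blastocyst (row ", which(bad)[1], ")")
  }
  class(outcomes) <- unique(c("outcome_table", class(outcomes)))
  invisible(outcomes)
}

stage_cols <- c(mii = "n_mii", cleavage = "n_cleaved",
                blastocyst = "n_blastocyst")

#' Pooled and per-replicate developmental stage rates
#'
#' Pools counts over replicates per treatment and reports the percentage of
#' cultured oocytes reaching each stage, plus the conditional percentage
#' relative to the previous stage (both denominators, since summaries of
#' such experiments use either). Percentages are reported to one decimal by
#' `print()`; full precision is kept in the returned values.
#'
#' @param outcomes an outcome table (see [validate_outcomes()]).
#' @return List of class `stage_rates`: `pooled` (treatment, stage,
#'   numerator, denominator, percent, percent_of_previous) and
#'   `per_replicate` (same rates per replicate row).
#' @export
stage_rates <- function(outcomes) {
  outcomes <- validate_outcomes(outcomes)
  pool <- stats::aggregate(
    outcomes[, c("n_cultured", "n_mii", "n_cleaved", "n_blastocyst")],
    by = list(treatment = outcomes$treatment), FUN = sum)
  pooled <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    num <- unlist(pool[i, stage_cols])
    prev <- unlist(pool[i, c("n_cultured", "n_mii", "n_cleaved")])
    denom <- pool$n_cultured[i]
    data.frame(
      treatment = pool$treatment[i],
      stage = names(stage_cols),
      numerator = unname(num),
      denominator = denom,
      percent = if (denom > 0) 100 * unname(num) / denom else NA_real_,
      percent_of_previous = ifelse(prev > 0, 100 * unname(num) / prev,
                                   NA_real_),
      stringsAsFactors = FALSE
    )
  }))
  per_rep <- do.call(rbind, lapply(names(stage_cols), function(st) {
    data.frame(
      treatment = outcomes$treatment, replicate = outcomes$replicate,
      stage = st, numerator = outcomes[[stage_cols[[st]]]],
      denominator = outcomes$n_cultured,
      percent = ifelse(outcomes$n_cultured > 0,
                       100 * outcomes[[stage_cols[[st]]]] /
                         outcomes$n_cultured, NA_real_),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(pooled = pooled, per_replicate = per_rep),
            class = "stage_rates")
}

#' @export
print.stage_rates <- function(x, ...) {
  p <- x$pooled
  for (trt in unique(p$treatment)) {
    cat(trt, ":\n")
    rows <- p[p$treatment == trt, ]
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("  %-10s %d / %d = %.1f%% of cultured\n", rows$stage[i],
                  rows$numerator[i], rows$denominator[i], rows$percent[i]))
    }
  }
  invisible(x)
}

#' Compare a stage rate between two treatments
#'
#' Pools counts into a 2x2 contingency table (reached stage vs not, by
#' treatment) and tests the proportions with a continuity-corrected
#' chi-square test, falling back to Fisher's exact test when any expected
#' cell is below 5.
#'
#' @param outcomes an outcome table with exactly two treatments.
#' @param stage one of `"mii"`, `"cleavage"`, `"blastocyst"`.
#' @return List of class `rate_comparison`: `stage`, `table` (2x2),
#'   `rates` (per treatment), `method`, `p_value`.
#' @export
compare_rates <- function(outcomes, stage = c("mii", "cleavage",
                                              "blastocyst")) {
  stage <- match.arg(stage)
  outcomes <- validate_outcomes(outcomes)
  trts <- unique(outcomes$treatment)
  if (length(trts) != 2L) {
    stop_validation("exactly two treatments required, got ", length(trts))
  }
  col <- stage_cols[[stage]]
  num <- tapply(outcomes[[col]], outcomes$treatment, sum)[trts]
  den <- tapply(outcomes$n_cultured, outcomes$treatment, sum)[trts]
  tab <- rbind(reached = num, not_reached = den - num)
  colnames(tab) <- trts
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    method <- "fisher_exact"
  } else {
    ht <- stats::chisq.test(tab, correct = TRUE)
    method <- "chi_square_continuity_corrected"
  }
  structure(list(stage = stage, table = tab,
                 rates = 100 * num / den, method = method,
                 p_value = ht$p.value),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("%s rate: %s %.1f%% vs %s %.1f%% (%s p = %.4g)\n",
              x$stage, colnames(x$table)[1], x$rates[1],
              colnames(x$table)[2], x$rates[2], x$method, x$p_value))
  invisible(x)
}

#' Compare blastocyst nuclei counts between treatments
#'
#' Per-treatment mean, standard error and n of nuclei per blastocyst, with
#' a two-sided equal-variance t-test.
#'
#' @param nuclei data frame with columns `treatment` and `count`, or a
#'   named list of count vectors.
#' @return List of class `nuclei_comparison`: `means`, `se`, `n`, `t`,
#'   `df`, `p_value`.
#' @export
compare_nuclei <- function(nuclei) {
  if (is.data.frame(nuclei)) {
    nuclei <- split(nuclei$count, nuclei$treatment)
  }
  if (length(nuclei) != 2L) {
    stop_validation("exactly two treatments required")
  }
  if (any(lengths(nuclei) < 2L)) {
    stop_validation("each treatment needs >= 2 blastocysts")
  }
  tt <- two_sample_t(nuclei[[1]], nuclei[[2]])
  structure(list(
    treatments = names(nuclei),
    means = vapply(nuclei, mean, numeric(1)),
    se = vapply(nuclei, function(x) stats::sd(x) / sqrt(length(x)),
                numeric(1)),
    n = lengths(nuclei),
    t = tt$t, df = tt$df, p_value = tt$p
  ), class = "nuclei_comparison")
}

#' @export
print.nuclei_comparison <- function(x, ...) {
  cat(sprintf("nuclei per blastocyst: %s %.1f +/- %.1f (n=%d) vs %s %.1f +/- %.1f (n=%d), p = %.4g\n",
              x$treatments[1], x$means[1], x$se[1], x$n[1],
              x$treatments[2], x$means[2], x$se[2], x$n[2], x$p_value))
  invisible(x)
}

#' Paired one-tailed densitometry test
#'
#' Paired one-tailed Student's t-test on replicate-matched densitometry
#' totals (the two band readings per lane are summed before this test).
#' The tail is a pre-registered choice and must be supplied; it is never
#' inferred from the data. With all differences zero the statistic is 0 and
#' the one-tailed p is 0.5.
#'
#' @param control,treated equal-length numeric vectors of per-replicate
#'   summed densitometry readings.
#' @param direction `"treated_less"` (alternative: treated < control) or
#'   `"treated_greater"`.
#' @return List of class `paired_test`: `mean_difference` (treated -
#'   control), `t`, `df`, `p_value`, `direction`.
#' @export
paired_densitometry_test <- function(control, treated,
                                     direction = c("treated_less",
                                                   "treated_greater")) {
  direction <- match.arg(direction)
  if (length(control) != length(treated)) {
    stop_validation("'control' and 'treated' must pair up (equal length)")
  }
  if (length(control) < 2L) {
    stop_validation("need >= 2 replicate pairs")
  }
  d <- treated - control
  n <- length(d)
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sd_d / sqrt(n))
  }
  p <- if (direction == "treated_less") stats::pt(t, n - 1)
       else stats::pt(t, n - 1, lower.tail = FALSE)
  structure(list(mean_difference = mean(d), t = t, df = n - 1,
                 p_value = p, direction = direction),
            class = "paired_test")
}
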