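#' Fit a primer-efficiency standard curve
#'
#' Ordinary least squares of Ct on log10(template concentration) over a
#' dilution series. Amplification efficiency is 10^(-1/slope) - 1: a slope
#' of -1/log10(2) (about -3.32 cycles per decade) means perfect doubling
#' per cycle, i.e. 100% efficiency.
#'
#' @param dilutions data frame with columns `concentration` (ng/uL) and
#'   `ct`; at least 3 distinct concentrations spanning >= 2 log10 units.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency` (fraction), `r_squared`, `n`.
#' @export
fit_standard_curve <- function(dilutions) {
  if (!all(c("concentration", "ct") %in% names(dilutions))) {
    stop_validation("dilutions need columns 'concentration' and 'ct'")
  }
  conc <- unique(dilutions$concentration)
  if (length(conc) < 3L) {
    stop_validation("invalid assay: need >= 3 distinct concentrations")
  }
  if (diff(range(log10(conc))) < 2) {
    stop_validation("invalid assay: dilution series must span >= 2 log10 ",
                    "units of concentration")
  }
  fit <- stats::lm(ct ~ log10(concentration), data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_validation("invalid assay: standard-curve slope must be negative")
  }
  sst <- sum((dilutions$ct - mean(dilutions$ct))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    r_squared = if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_,
    n = nrow(dilutions)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.3f, efficiency %.1f%%, R^2 %.4f\n",
              x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Comparative-CT (2^-ddCt) relative expression
#'
#' Replicate wells are averaged on the Ct scale per (gene, sample); the
#' target is normalized to the housekeeping gene (delta Ct) and then to a
#' reference sample (delta delta Ct); relative quantity is 2^(-ddCt). The
#' reference sample's rq is exactly 1 by construction. Samples missing the
#' housekeeper are excluded with a warning; a missing reference sample is
#' an error.
#'
#' @param plate data frame with columns gene, sample, ct (and optionally
#'   group, carried through).
#' @param target target gene id.
#' @param housekeeper housekeeping gene id (e.g. YWHAG).
#' @param reference_sample sample whose expression anchors rq = 1. The
#'   reference can differ per target gene (different reference cDNA pools),
#'   so it is always passed explicitly.
#' @return Data frame: gene, sample, group (NA if absent from the plate),
#'   delta_ct, delta_delta_ct, rq.
#' @export
delta_delta_ct <- function(plate, target, housekeeper, reference_sample) {
  for (g in c(target, housekeeper)) {
    if (!g %in% plate$gene) {
      stop_validation("gene '", g, "' not on the plate")
    }
  }
  mean_ct <- stats::aggregate(ct ~ gene + sample, data = plate, FUN = mean)
  tgt <- mean_ct[mean_ct$gene == target, ]
  hk <- mean_ct[mean_ct$gene == housekeeper, ]
  no_hk <- setdiff(tgt$sample, hk$sample)
  if (length(no_hk)) {
    warning("sample(s) without housekeeper measurements excluded: ",
            paste(no_hk, collapse = ", "), call. = FALSE)
    tgt <- tgt[!tgt$sample %in% no_hk, ]
  }
  if (!reference_sample %in% tgt$sample) {
    stop_validation("reference sample '", reference_sample,
                    "' absent for gene '", target, "'")
  }
  dct <- tgt$ct - hk$ct[match(tgt$sample, hk$sample)]
  ddct <- dct - dct[tgt$sample == reference_sample]
  group <- if ("group" %in% names(plate)) {
    plate$group[match(tgt$sample, plate$sample)]
  } else NA_character_
  data.frame(
    gene = target, sample = tgt$sample, group = group,
    delta_ct = dct, delta_delta_ct = ddct, rq = 2^(-ddct),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare relative expression between two groups
#'
#' Group means and standard errors of the 2^-ddCt quantities, with a
#' two-sided equal-variance t-test (with one two-level factor this is the
#' same comparison a one-factor GLM's least-squares means would give).
#' Sample skewness and a Shapiro-Wilk normality p-value of the rq values
#' are reported alongside as distributional diagnostics; no automatic
#' transformation is applied.
#'
#' @param rqs data frame from [delta_delta_ct()] with a `group` column, or
#'   a numeric rq vector.
#' @param groups group label per rq value (taken from `rqs$group` when
#'   omitted).
#' @return List of class `expression_comparison`: per-group `means`, `se`,
#'   `n`, plus `p_value`, `t`, `df`, `skewness`, `shapiro_p`.
#' @export
compare_expression <- function(rqs, groups = NULL) {
  if (is.data.frame(rqs)) {
    if (is.null(groups)) groups <- rqs$group
    rqs <- rqs$rq
  }
  if (length(groups) != length(rqs)) {
    stop_validation("'groups' must label every rq value")
  }
  lv <- unique(groups)
  if (length(lv) != 2L) {
    stop_validation("exactly two groups required")
  }
  xs <- split(rqs, factor(groups, levels = lv))
  ns <- lengths(xs)
  if (any(ns < 2L)) {
    stop_validation("each group needs >= 2 samples")
  }
  tt <- two_sample_t(xs[[1]], xs[[2]])
  structure(list(
    groups = lv,
    means = vapply(xs, mean, numeric(1)),
    se = vapply(xs, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    n = ns,
    t = tt$t, df = tt$df, p_value = tt$p,
    skewness = sample_skewness(rqs),
    shapiro_p = if (length(rqs) >= 3L && stats::sd(rqs) > 0) {
      stats::shapiro.test(rqs)$p.value
    } else NA_real_
  ), class = "expression_comparison")
}

# pooled-variance two-sided two-sample t; p = NA when pooled variance is 0
two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  df <- nx + ny - 2
  if (sp2 == 0) return(list(t = NA_real_, df = df, p = NA_real_))
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("relative expression: %s %.2f +/- %.2f (n=%d) vs %s %.2f +/- %.2f (n=%d), p = %.4g\n",
              x$groups[1], x$means[1], x$se[1], x$n[1],
              x$groups[2], x$means[2], x$se[2], x$n[2], x$p_value))
  invisible(x)
}

#' Direction concordance between sequencing and qPCR
#'
#' For each gene measured on both platforms, compares the direction of the
#' differential signal: by sequencing, the called direction from the
#' three-filter procedure; by qPCR, the group with the higher mean rq when
#' the comparison is significant at `alpha`. Genes significant on neither
#' platform are indeterminate and excluded from the agreement denominator;
#' gene ids that cannot be mapped to a transcript are listed, not silently
#' dropped.
#'
#' @param seq_de a `de_result` from [differential_test()].
#' @param qpcr_results data frame with one row per gene: `gene`, `p_value`,
#'   and `higher_in` (group with the larger mean rq).
#' @param gene_map named character vector mapping gene id -> transcript id
#'   (identity map when `NULL`).
#' @param alpha significance cutoff for the qPCR comparison.
#' @return List of class `concordance`: `table` (gene, seq_direction,
#'   qpcr_direction, status), `agreement` (fraction among determinate
#'   genes), `unmapped` genes.
#' @export
platform_concordance <- function(seq_de, qpcr_results, gene_map = NULL,
                                 alpha = 0.05) {
  genes <- qpcr_results$gene
  tx <- if (is.null(gene_map)) genes else unname(gene_map[genes])
  idx <- match(tx, seq_de$transcript_id)
  unmapped <- genes[is.na(idx)]
  rows <- lapply(which(!is.na(idx)), function(i) {
    de <- seq_de[idx[i], ]
    seq_dir <- if (isTRUE(de$called)) de$direction else NA_character_
    q <- qpcr_results[i, ]
    qpcr_dir <- if (!is.na(q$p_value) && q$p_value <= alpha) q$higher_in
                else NA_character_
    status <- if (is.na(seq_dir) || is.na(qpcr_dir)) "indeterminate"
              else if (seq_dir == qpcr_dir) "agree" else "disagree"
    data.frame(gene = genes[i], seq_direction = seq_dir,
               qpcr_direction = qpcr_dir, status = status,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), seq_direction = character(),
               qpcr_direction = character(), status = character())
  determinate <- tab$status != "indeterminate"
  structure(list(
    table = tab,
    agreement = if (any(determinate)) mean(tab$status[determinate] == "agree")
                else NA_real_,
    unmapped = unmapped
  ), class = "concordance")
}
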