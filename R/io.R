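#' Read a run-level count table and its manifest
#'
#' The count TSV has transcripts in the first column and one column per
#' sequencing run; the manifest TSV maps run_id -> sample_id -> group.
#' Counts are validated as non-negative integers (a "3.5" is rejected with
#' its coordinates) and run totals are recomputed, never trusted from file.
#'
#' @param counts_tsv path to the count TSV.
#' @param manifest_tsv path to the manifest TSV.
#' @return A `run_counts` object.
#' @export
read_counts <- function(counts_tsv, manifest_tsv) {
  raw <- utils::read.delim(counts_tsv, check.names = FALSE,
                           stringsAsFactors = FALSE)
  manifest <- utils::read.delim(manifest_tsv, stringsAsFactors = FALSE)
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- ids
  run_counts(mat, manifest)
}

#' Write a run-level count table and manifest as TSV
#'
#' Inverse of [read_counts()]; the written files round-trip exactly.
#'
#' @param runs a `run_counts` object.
#' @param counts_tsv,manifest_tsv output paths.
#' @export
write_counts <- function(runs, counts_tsv, manifest_tsv) {
  stopifnot(inherits(runs, "run_counts"))
  df <- data.frame(transcript_id = rownames(runs$counts),
                   runs$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(runs$manifest, manifest_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_tsv, manifest_tsv))
}

#' Write a normalized count matrix with a provenance sidecar
#'
#' @param matrix a `count_matrix`.
#' @param tsv output TSV path; a JSON sidecar `<tsv>.json` records the
#'   normalization factors and group labels.
#' @export
write_count_matrix <- function(matrix, tsv) {
  stopifnot(inherits(matrix, "count_matrix"))
  df <- data.frame(transcript_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(groups = as.list(matrix$groups),
         normalization_factors = as.list(matrix$factors)),
    paste0(tsv, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}

#' Pipeline configuration
#'
#' Collects file paths and analysis parameters. The defaults are the
#' published procedure's operating point: p-value cutoff 0.1, 2-fold
#' minimum change, 95% confidence for the detection threshold, aromatase
#' (CYP19A1) as the cumulus contamination marker and YWHAG as the qPCR
#' housekeeper.
#'
#' @param counts_tsv,manifest_tsv count table and run manifest paths.
#' @param gmt optional GMT gene-set file for the enrichment stage.
#' @param alpha t-test p-value cutoff.
#' @param min_fold minimum fold change.
#' @param confidence confidence level of the detection threshold.
#' @param marker_id contamination-marker transcript id.
#' @param housekeeper_id qPCR housekeeping gene id.
#' @param allow_contaminated proceed past a failed contamination check
#'   (logged) instead of halting.
#' @param out_dir optional directory for per-stage artifacts.
#' @param seed integer recorded in the report for provenance.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_tsv, manifest_tsv, gmt = NULL,
                            alpha = 0.1, min_fold = 2.0, confidence = 0.95,
                            marker_id = "CYP19A1", housekeeper_id = "YWHAG",
                            allow_contaminated = FALSE, out_dir = NULL,
                            seed = NULL) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(min_fold, "min_fold", lower = 1)
  check_number(confidence, "confidence", lower = 0, upper = 1)
  structure(list(counts_tsv = counts_tsv, manifest_tsv = manifest_tsv,
                 gmt = gmt, alpha = alpha, min_fold = min_fold,
                 confidence = confidence, marker_id = marker_id,
                 housekeeper_id = housekeeper_id,
                 allow_contaminated = allow_contaminated,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the sequencing-comparison pipeline end to end
#'
#' Stages, in the order the analysis prescribes: read counts; compute
#' library-size normalization factors; derive the detection threshold from
#' between-run variance; normalize and sum technical runs; check the
#' contamination marker (a failed check halts the pipeline unless
#' `allow_contaminated` is set); run the three-filter differential test;
#' summarize the call funnel; optionally run directional gene-set
#' over-representation. Every stage's inputs and outputs are logged via
#' `message()` and collected into a single report; given the same inputs
#' the report is identical (no stage is stochastic).
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_report`: `config`, `factors`,
#'   `threshold`, `contamination`, `de` (full `de_result`), `de_summary`,
#'   `enrichment` (per direction, when a GMT is given).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  runs <- read_counts(config$counts_tsv, config$manifest_tsv)
  message("read ", nrow(runs$counts), " transcripts x ", ncol(runs$counts),
          " runs")
  factors <- compute_normalization_factors(runs)
  threshold <- detection_threshold(runs, factors,
                                   confidence = config$confidence)
  message("detection threshold: ", threshold$threshold, " reads")
  cm <- normalize_and_sum(runs, factors)
  contamination <- contamination_check(cm, config$marker_id, threshold)
  message("contamination check (", config$marker_id, "): ",
          if (contamination$pass) "pass" else "FAIL")
  if (!contamination$pass && !config$allow_contaminated) {
    stop_contamination("contamination marker '", config$marker_id,
                       "' at or above the detection threshold; halting ",
                       "before differential calling")
  }
  de <- differential_test(cm, alpha = config$alpha,
                          min_fold = config$min_fold, min_reads = threshold)
  de_summary <- summarize_calls(de)
  message("differential calls: ", de_summary$n_called, " of ",
          de_summary$n_tested, " transcripts (",
          paste(sprintf("%s: %d", names(de_summary$by_direction),
                        de_summary$by_direction), collapse = ", "), ")")
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    sets <- load_gmt(config$gmt)
    universe <- de$transcript_id[de$passes_threshold]
    enrichment <- lapply(names(de_summary$by_direction), function(g) {
      query <- de$transcript_id[de$called & !is.na(de$direction) &
                                  de$direction == g]
      hypergeometric_enrichment(query, sets, universe)
    })
    names(enrichment) <- paste0("higher_in_", names(de_summary$by_direction))
  }
  report <- structure(list(config = config, factors = factors,
                           threshold = threshold,
                           contamination = contamination,
                           de = de, de_summary = de_summary,
                           enrichment = enrichment),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write per-stage pipeline artifacts
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$de, file.path(dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$enrichment)) {
    for (nm in names(report$enrichment)) {
      utils::write.table(report$enrichment[[nm]],
                         file.path(dir, paste0("enrichment_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cfg <- report$config
  jsonlite::write_json(list(
    parameters = list(alpha = cfg$alpha, min_fold = cfg$min_fold,
                      confidence = cfg$confidence,
                      marker_id = cfg$marker_id, seed = cfg$seed),
    normalization_factors = as.list(report$factors),
    detection_threshold = unclass(report$threshold),
    contamination = list(marker = report$contamination$marker_id,
                         group_means = as.list(report$contamination$group_means),
                         pass = report$contamination$pass),
    de_summary = report$de_summary
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
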