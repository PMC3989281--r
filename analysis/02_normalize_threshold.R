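#!/usr/bin/env Rscript
# Normalize run depths by the minimum-total ratio scheme, sum technical
# runs into biological-replicate values, derive the detection threshold
# from the pooled between-run variance, and check the cumulus contamination
# marker (aromatase) against it.

suppressPackageStartupMessages(library(ivmseq))
dir.create("results", showWarnings = FALSE)

runs <- read_counts("results/sim/counts.tsv", "results/sim/manifest.tsv")
factors <- compute_normalization_factors(runs)
cat("normalization factors:\n")
print(round(factors, 3))

thr <- detection_threshold(runs, factors)
print(thr)

cm <- normalize_and_sum(runs, factors)
write_count_matrix(cm, "results/count_matrix.tsv")
verdict <- contamination_check(cm, "CYP19A1", thr)
print(verdict)
if (!verdict$pass) stop("contamination gate failed; halting the analysis")

jsonlite::write_json(
  list(factors = as.list(round(factors, 6)),
       detection_threshold = unclass(thr),
       contamination = list(marker = verdict$marker_id,
                            group_means = as.list(verdict$group_means),
                            pass = verdict$pass)),
  "results/normalization.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/count_matrix.tsv and results/normalization.json\n")
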