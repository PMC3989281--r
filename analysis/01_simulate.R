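#!/usr/bin/env Rscript
# Generate the synthetic study inputs: run-level counts with the design of
# the sequencing experiment (2 groups x 3 biological replicates x 2
# technical runs), a planted ground truth, triplicate qPCR plates for three
# validation genes, a primer dilution series, and replicated maturation
# outcomes. Everything downstream reads these files.

suppressPackageStartupMessages(library(ivmseq))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20140101

spec <- sim_spec(n_transcripts = 5000, de_fraction = 0.05,
                 fold_change_set = c(2, 4, 8), seed = seed)
sim <- generate_counts(spec)
write_counts(sim$runs, file.path(out, "counts.tsv"),
             file.path(out, "manifest.tsv"))
write.table(sim$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("counts: %d transcripts x %d runs, %d planted DE transcripts\n",
            nrow(sim$runs$counts), ncol(sim$runs$counts), nrow(sim$truth)))
cat(sprintf("run totals span %.2fx (library-size variation to be undone ",
            max(sim$runs$totals) / min(sim$runs$totals)),
    "by normalization)\n", sep = "")

# qPCR plates: three genes planted at the fold changes the sequencing arm
# should also see, plus a null gene
plate <- generate_ct_plate(c(DVL1 = 4, WNT7A = 3, FZD4 = 2.5, ATG4 = 1),
                           noise_sd = 0.15, seed = seed + 1)
write.csv(plate, file.path(out, "ct_plate.csv"), row.names = FALSE)
dil <- generate_dilution_series(slope = -3.45, intercept = 22,
                                noise_sd = 0.05, seed = seed + 2)
write.csv(dil, file.path(out, "dilution_series.csv"), row.names = FALSE)
cat(sprintf("qPCR plate: %d wells, dilution series at %s ng/uL\n",
            nrow(plate), paste(dil$concentration, collapse = "/")))

# maturation outcomes: four replicates per arm at the published rates
oc <- generate_outcomes(seed = seed + 3)
write.csv(oc$outcomes, file.path(out, "outcomes.csv"), row.names = FALSE)
write.csv(oc$nuclei, file.path(out, "nuclei.csv"), row.names = FALSE)
cat(sprintf("outcomes: %d replicate rows, %d blastocysts with nuclei counts\n",
            nrow(oc$outcomes), nrow(oc$nuclei)))
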