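#!/usr/bin/env Rscript
# Direction-specific gene-set over-representation on the differential
# calls. The gene sets are synthetic: one set is seeded with planted
# differential transcripts (so it should enrich), the others are random
# draws from the universe (so they should not).

suppressPackageStartupMessages(library(ivmseq))
set.seed(20140104)

de <- read.delim("results/de_results.tsv")
truth <- read.delim("results/sim/ground_truth.tsv")
universe <- de$transcript_id[de$passes_threshold]

planted_in_universe <- intersect(truth$transcript_id, universe)
sets <- c(
  list(planted_pathway = c(sample(planted_in_universe, 30),
                           sample(setdiff(universe, planted_in_universe),
                                  20))),
  setNames(lapply(1:5, function(i) sample(universe, 50)),
           paste0("random_set_", 1:5))
)
gmt <- "results/synthetic_sets.gmt"
writeLines(vapply(names(sets), function(nm) {
  paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t")
}, character(1)), gmt)

for (g in unique(na.omit(de$direction))) {
  query <- de$transcript_id[de$called & !is.na(de$direction) &
                              de$direction == g]
  rows <- hypergeometric_enrichment(query, load_gmt(gmt), universe)
  cat(sprintf("\ntranscripts higher in %s (query n = %d):\n", g,
              length(query)))
  print(rows, row.names = FALSE)
  write.table(rows, sprintf("results/enrichment_higher_in_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nwrote results/enrichment_higher_in_*.tsv\n")
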