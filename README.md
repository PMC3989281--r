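# ivmseq

Oocytes matured in the lab (*in vitro* maturation, IVM) give poorer embryos
than oocytes matured inside the animal (*in vivo*, IVV), and one way to ask
why is to compare their transcriptomes. `ivmseq` implements, as a tested R
package plus a set of analysis drivers, the complete desk-side analysis
chain for such a comparison in the pig: run-level RNA-seq count
normalization, a read-count detection threshold, differential-transcript
calling, a cumulus-cell contamination check, gene-set over-representation,
comparative-CT qPCR validation, and embryo-outcome statistics for a
follow-up maturation experiment (WNT inhibition with DKK1). A seeded
synthetic-data generator reproduces the experiment's replicate structure —
2 treatment groups × 3 biological replicates (pools of 10 oocytes) × 2
technical sequencing runs — with known ground truth, so every stage is
testable end to end.

## The analysis chain

1. **Normalization.** Each sequencing run *i* gets a factor
   `f_i = min_j(total_j) / total_i`, where `total` is the run's count of
   alignable reads; scaling by `f_i` brings every run to the depth of the
   shallowest run. The two technical runs of each biological replicate are
   then summed (after normalization, kept as reals), giving one value per
   transcript per replicate.
2. **Detection threshold.** The between-run variance of normalized counts
   is pooled over all run pairs and averaged over transcripts with any
   reads. The threshold is the smallest integer mean `m` with
   `m − t_{(1+c)/2, df} · √(s²_pooled / n) > 0` (confidence `c = 0.95`,
   `n` = replicates per group): the smallest mean read count statistically
   greater than zero.
3. **Contamination check.** Aromatase (*CYP19A1*), highly abundant in
   cumulus cells but not oocytes, must stay below the threshold in every
   group; otherwise the pipeline halts before calling.
4. **Differential calling.** Per transcript: group means, fold change
   `max(m_A, m_B)/min(m_A, m_B)`, and a two-sided pooled-variance Student's
   t-test on replicate values. Called ⇔ larger group mean ≥ threshold,
   `p ≤ 0.1`, and fold ≥ 2. No multiple-testing correction (a documented
   property of the procedure, not an oversight of the implementation).
5. **Enrichment.** Upper-tail hypergeometric over-representation of each
   direction's calls in GMT gene sets, against the threshold-passing
   universe.
6. **qPCR validation.** Primer efficiency `10^(−1/slope) − 1` from a
   dilution-series standard curve; relative expression by `2^-ΔΔCT` against
   the *YWHAG* housekeeper and an explicit reference sample; pooled-t group
   comparison; per-gene direction concordance between platforms.
7. **Outcomes.** Maturation/cleavage/blastocyst rates from pooled counts
   with 2×2 chi-square (or Fisher) comparisons, nuclei-per-blastocyst
   t-test, and a paired one-tailed t-test for western densitometry.

## Worked example

```r
library(ivmseq)

sim <- generate_counts(sim_spec(n_transcripts = 500, seed = 42))
thr <- detection_threshold(sim$runs)
print(thr)
#> detection threshold: 95 reads (95% CI half-width 94.937; pooled variance 4091.9282, df 5, n 3)

cm <- normalize_and_sum(sim$runs)
print(contamination_check(cm, "CYP19A1", thr))
#> contamination check for CYP19A1 - PASS
#>   mean normalized reads in IVM: 0.00 (threshold 95)
#>   mean normalized reads in IVV: 0.19 (threshold 95)

de <- differential_test(cm, alpha = 0.1, min_fold = 2, min_reads = thr)
summarize_calls(de)$n_called
#> [1] 32
```

The threshold (95 reads here) is a property of the data: it grows with the
technical between-run variance, which this simulation draws at higher
overall expression variance than a real lane would show; on the published
data the same construction gave single-digit thresholds. The contamination
marker sits two orders of magnitude below it, so the pipeline proceeds and
calls 32 transcripts — close to the 50 planted, with the shortfall among
low-expression transcripts the threshold filter removes.

The numbered drivers under `analysis/` run the whole chain on synthetic
data and on the published summary tables shipped under `inst/extdata/`
(run them from the repository root in order):

```sh
Rscript analysis/01_simulate.R          # inputs -> results/sim/
Rscript analysis/02_normalize_threshold.R
Rscript analysis/03_differential_calls.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_qpcr_validation.R
Rscript analysis/06_embryo_outcomes.R
```

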