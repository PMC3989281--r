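---
title: "Methods: how ivmseq normalizes, thresholds, calls and validates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how ivmseq normalizes, thresholds, calls and validates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmseq)
```

`ivmseq` compares transcript abundance between in vitro matured (IVM) and
in vivo matured (IVV) oocytes from run-level RNA-seq counts, validates the
calls by comparative-CT qPCR, and analyses the outcomes of a follow-up
maturation experiment. This vignette records the statistical model behind
each stage, the parameters that matter, and the design choices that were
genuinely open, so that a reader can audit — or disagree with — each one.

## The count model and the experimental design

The design the package assumes, and that its generator reproduces, is two
treatment groups, three biological replicates per group (each a pool of 10
oocytes), and two technical sequencing runs per replicate: twelve run-level
count vectors over a shared transcript universe. Biological replication is
at the pool level; the technical runs exist only to estimate machine-level
noise, and are summed away after normalization.

The synthetic generator draws counts from a negative binomial with a shared
dispersion $\phi$ (variance $\mu + \phi\mu^2$). The experiment itself
states no noise model, so this is a modelling choice, made once: NB is the
standard over-dispersed count model for RNA-seq, and $\phi = 0$ degenerates
to Poisson, which gives analytic checks (the test suite verifies the
Poisson mean at $\mu = 100$ over $10^4$ draws). Per-transcript baseline
means are log-normal (`meanlog = log(50)`, `sdlog = 1.5` by default: a
median of 50 reads with a realistically heavy right tail). Technical runs
are independent NB draws at run-specific depth factors drawn uniformly from
`library_size_range` (default 0.7–1.3, a ~1.9× depth spread across runs) —
independent draws, not a split of one draw, so run totals can be controlled
independently when testing normalization. Planted differential transcripts
get a fold from `fold_change_set` with the higher group chosen by a fair
coin, since real comparisons report both directions. One transcript is
labelled as the cumulus contamination marker and simulated at mean 0.3
reads, mirroring the expected negative aromatase check.

What the generator does *not* emulate: transcript-length and GC effects,
correlated transcripts, sample-specific dispersions, ambiguous-alignment
filtering, or any cumulus-cell biology (the marker is just a labelled
low-mean transcript). Passing tests therefore show that the chain is
correct under its stated model, not that the model captures every property
of a real lane.

## Normalization and the detection threshold

Normalization is the minimum-ratio scheme: factor
$f_i = \min_j(\mathrm{total}_j)/\mathrm{total}_i$ per sequencing run, which
rescales every run to the shallowest run's depth. "Sample" here means
*sequencing run*, not biological replicate: the two runs of each replicate
are summed only after normalization, and normalizing after summing would
make that ordering vacuous. Normalized values are kept as reals; re-rounding
would break the mass-conservation identity
$\sum_t \mathrm{entry}(t,s) = \sum_{r \in s} f_r \cdot \mathrm{total}_r$
that the tests assert to 1e-9 relative.

The detection threshold asks: how many reads must a transcript average
before that average is statistically above zero, given machine noise? The
between-run variance of normalized counts is computed per transcript within
each replicate's run pair, averaged over pairs and then over transcripts.
Three choices here were open and are worth recording:

* **One pooled variance, not per-transcript.** A single global estimate
  yields a single experiment-wide integer threshold, which is what the
  procedure reports; per-transcript intervals could not produce one number.
  The cost is that the pooled variance is dominated by high-expression
  transcripts, whose absolute between-run variance is largest — the
  threshold therefore scales with overall expression variance and should be
  read as a property of each dataset, not a constant.
* **All-zero transcripts are excluded** from pooling: they carry no
  technical-noise information and would deflate the threshold.
* **Student-t quantile, df = (number of run pairs) − 1.** With six run
  pairs the df is small, so the t quantile is materially wider than the
  normal; the df and pooled variance are returned in the
  `detection_threshold` object so either choice can be recomputed.

The threshold itself is the smallest positive integer $m$ with
$m - t_{(1+c)/2,\,df}\sqrt{s^2_{\mathrm{pooled}}/n} > 0$, found in closed
form (`floor(half-width) + 1`) and verified in the tests against a
brute-force integer scan; zero pooled variance gives threshold 1 (any
positive mean beats a zero-width interval).

The contamination check compares the marker's per-group mean normalized
reads to the threshold; a marker at or above it in any group halts the
pipeline before calling (overridable, logged), and an absent marker is an
error rather than a silent pass.

## The three-filter caller

A transcript is called differential when all three hold: larger group mean
at or above the detection threshold; two-sided **equal-variance** Student's
t on the three replicate values per group with $p \le 0.1$; fold change
$\max(m_A,m_B)/\min(m_A,m_B) \ge 2$. Open choices, resolved as follows:

* *Which group must reach the threshold?* The default is the larger group
  mean (`threshold_rule = "either"`): requiring both groups would exclude
  exactly the on/off transcripts the procedure is most interested in. The
  rule is switchable (`"both"`, `"mean"`) because the original wording is
  ambiguous.
* *Student or Welch?* Classic pooled-variance Student's t (df
  $n_A+n_B-2$), matching the named test; the implementation is verified
  against the closed-form formula to 1e-10 and against `stats::t.test
  (var.equal = TRUE)` as a second route.
* *Zero variance.* When both groups are constant the t statistic is
  undefined: p is `NA`, `passes_p` is `FALSE`, never a crash. If only one
  group is constant the pooled t is well defined and is used — otherwise
  on/off transcripts (one mean zero, fold $+\infty$) could never be called.
* *Both means zero* gives an undefined fold and no call.
* *No multiple-testing correction*, faithfully to the procedure; with
  $\alpha = 0.1$ over thousands of transcripts the expected false-call
  count is material, which is why the fold and threshold filters carry most
  of the specificity. The null-calibration test verifies the p-filter
  passes at its nominal rate (within ±50% of 0.1 over 200 null
  simulations), and the false calls among high-expression null transcripts
  are then removed almost entirely by the 2-fold filter.

All transcripts are returned with all three flags so the filter funnel is
auditable; `summarize_calls()` reports calls by direction and independent
failure counts per filter.

## Enrichment

Over-representation is the upper-tail hypergeometric
$P(X \ge k)$ for overlap $k$ between a direction's calls and each gene set,
over a stated universe. The default universe is the threshold-passing
transcripts — the set the caller could actually have selected from — and is
switchable to all transcripts. Enrichment runs separately per direction
because direction-specific pathway lists are the output of interest. This
is a generic replacement for annotation-service enrichment: external
databases and modified statistics are out of scope, so published
pathway p-values are context, not targets. Tests verify the p-values
against exhaustive enumeration of all draws for universes up to 25.

## qPCR quantification

Efficiency comes from an OLS fit of Ct on $\log_{10}$(concentration) over a
dilution series spanning at least two decades (default concentrations 5,
0.5, 0.05 ng/µL); efficiency $= 10^{-1/\mathrm{slope}} - 1$, with slope
$-1/\log_{10} 2 \approx -3.32$ meaning perfect doubling. Efficiency is
reported but **not** used to correct the quantities: relative expression is
plain $2^{-\Delta\Delta C_T}$, as in the validated procedure (a
corrected-efficiency mode would be a different estimator and is not
implemented). Wells are averaged on the Ct scale — standard
comparative-CT practice — before differencing against the *YWHAG*
housekeeper and an explicitly supplied reference sample. The reference is a
per-gene argument, never a global default, because validation panels
routinely use different reference cDNA pools for different genes, which
puts their rq values on different scales. Group comparison is the pooled
two-sample t (equivalent to a two-level one-factor GLM's LSMeans contrast);
skewness and a Shapiro-Wilk p accompany the result as diagnostics, with no
automatic transformation since none is prescribed. The ddCt chain is
invariant to a per-sample machine offset and anchors the reference sample
at rq = 1 exactly; both are asserted in the tests.

## Outcome statistics

Stage rates are pooled over replicates per treatment; both denominators
(per cultured oocyte and per previous stage) are reported because summary
tables use either convention. Treatment comparisons use the pooled 2×2
table with a continuity-corrected chi-square, switching to Fisher's exact
test when any expected cell is below 5. This replaces a repeated-measures
GLM/LSMeans analysis: per-replicate raw data for the published experiment
are unavailable, while the pooled counts are published and reproduce the
published MII percentages exactly (483/661 → 73.1%, 446/543 → 82.1%), so
pooling is the faithful desk-scale surrogate — the published cleavage and
blastocyst least-squares means do not equal pooled ratios and are
deliberately not reproduction targets. Nuclei counts are compared by
pooled t; densitometry by a paired one-tailed t whose direction must be
supplied by the caller (a pre-registered choice, never inferred from the
data). The all-zero-differences case returns $t = 0$, $p = 0.5$ rather
than an error.

## Problem sizes and determinism

The test suite and the acceptance script run the chain at the design scale
(12 runs) with transcript counts between 60 and 5,000 per simulation, and
Monte-Carlo sweeps of 20–200 seeds per property — sizes chosen so the full
suite completes in well under a minute while leaving Monte-Carlo error far
inside the asserted margins. All generators take an explicit integer seed,
restore the caller's RNG state (`withr::with_seed`), and are bit-reproducible;
the pipeline itself contains no randomness, so a fixed input gives an
identical report.

## Known limitations

* The detection threshold inherits the pooled-variance construction's
  sensitivity to the expression distribution; datasets with heavier
  high-expression tails get materially higher thresholds.
* The caller's t-test at $n = 3$ per group leans on approximate normality
  of normalized, summed counts; calibration holds at high expression and
  degrades for means near the threshold.
* The contamination verdict is a point comparison of group means to the
  threshold, with no uncertainty statement of its own.
* Enrichment treats transcripts as exchangeable; no length or abundance
  bias correction.
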