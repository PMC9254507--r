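---
title: "Statistical methods of the lfqpipe pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the lfqpipe pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
```

# The analysis problem

Label-free quantitative proteomics of a paired immune-cell cohort
produces a wide matrix of normalized protein abundances: one row per
protein, one column per sample, where each of the cohort's donors
(patients with multiple sclerosis, MS, and healthy controls, HC)
contributes an unstimulated and an in-vitro-activated (stimulated)
CD4+ T cell sample. Two features of such data drive the design of this
pipeline: abundances are approximately log-normal, and missingness is
*not at random* — low-abundance proteins drop below the detection limit,
so a missing cell is informative about a low value.

# Preprocessing

The preprocessing order is fixed: contaminant removal, log2 transform,
valid-value filtering, imputation. Each step appends to the matrix's
provenance log, and observed values are never modified after the log2
transform.

**Valid-value filter.** A protein is retained iff, in at least one of
the four group × condition strata, the fraction of samples with an
observed value is at least `min_frac` (default 0.7, inclusive `>=`).
Filtering within strata rather than globally keeps proteins expressed
only after activation, or only in one group — exactly the proteins the
stratified tests are for.

**Downshifted-normal imputation.** Missing cells are drawn per sample
column from `Normal(m - downshift * s, (width * s)^2)` where `m` and `s`
are the column's observed mean and SD; defaults `width = 0.3`,
`downshift = 1.8` are the values in widespread use for left-censored
LFQ data. Imputation is per column rather than matrix-global: the
detection limit is a property of a run (sample), not of the experiment,
and per-column imputation preserves sample-specific abundance
distributions. The draw is seeded; identical seed and input give
bit-identical output. Columns with fewer than two observed values have
no defined `s` and raise an error rather than guessing.

An optional per-sample median centering (`median_center()`) exists but
is off by default: input abundances are assumed already normalized
upstream, and re-normalizing silently would hide upstream problems.

# Stratified differential expression

**Activation contrast (paired).** For each protein, a two-sided paired
Student's t-test on per-donor (stimulated − unstimulated) log2
differences — algebraically a one-sample t-test on the difference
vector, which is the oracle the test suite checks against. The paired
design removes the donor random effect, which is why the generator
plants one (see below). The fold-change estimate is the mean paired
difference.

**Group contrast (Welch).** MS vs HC within one condition uses Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom;
patient and control groups have no pairing structure and no reason to
share a variance. `log2_fc` is the difference of group means of imputed
log2 intensities; group medians and SDs are also reported since result
tables conventionally print medians, but the mean difference is the
estimator (median differences do not reproduce mean-based fold
changes).

Both tests are computed vectorized from row means and variances rather
than by looping `t.test()` over proteins: the resampling validation
performs ~100 × 5,000 tests per condition, and the row-wise formulas
make that interactive. The test suite verifies exact numerical
agreement with `stats::t.test` on fixtures.

**Degenerate ties.** A protein whose values are all identical across
the compared samples has zero variance and an undefined t statistic.
The pipeline's rule: p = 1 and log2_fc = 0 (no evidence of change).
Zero variance with *different* means (perfect separation, possible only
in constructed data) reports p = 0. After imputation exact ties are
vanishingly rare in real data; the rule exists so synthetic edge cases
cannot crash a 100-iteration validation run.

**Multiple testing.** Benjamini–Hochberg step-up adjustment via
`stats::p.adjust`, applied strictly within one analysis stratum
(activation all-donors, activation HC-only, activation MS-only,
MS-vs-HC unstimulated, MS-vs-HC stimulated) — never across strata,
which would couple unrelated hypothesis families. Significance
thresholds are inclusive (`adj_p <= alpha`); defaults are 0.01 for the
activation analyses and 0.05 for the group analyses. The suite checks
`p.adjust` against an independent brute-force step-up implementation on
random vectors.

# PCA and the influential-loading rule

PCA uses samples as observations and the selected (typically
DE-significant) proteins as variables, centered and scaled to unit
variance — an eigendecomposition of the correlation structure
(`stats::prcomp`; the test suite cross-checks against an explicit
`eigen(cor(X))` oracle at 1e-8). Standardization is the default and a
switch: the uniform-contribution interpretation of the loading cutoff
presumes variables on comparable scales, which raw log2 intensities
spanning ten units are not.

If all `p` variables contributed equally to a unit-norm loading vector,
every loading would have magnitude `sqrt(1/p)`. Loadings at or above
this cutoff are flagged *influential*, inclusively — required so that
the exact uniform-contribution case flags all variables. The comparison
carries a 1e-10 numerical tolerance so that boundary cases (e.g.
loadings of exactly ±1/√2 versus a cutoff computed as √(1/2)) are not
decided by floating-point rounding. When checking counts against
loading tables printed at 3 decimals, the cutoff must be rounded to the
same precision before thresholding; the bundled 33-protein table flags
15 proteins at cutoff 0.174, including one sitting exactly on the
boundary.

Component signs are arbitrary in any PCA; for reproducibility across
linear-algebra backends each component is flipped, if necessary, so its
largest-magnitude loading is positive.

Zero-variance variables cannot be standardized and raise an error
naming the protein — silently dropping them would desynchronize the
loading table from the requested protein set.

# Split-cohort resampling validation

Each of `n_iterations` (default 100) iterations: (1) draw
`n_per_group` (default 10) donors per group uniformly without
replacement as the discovery half — donors, not samples, are split, so
no leakage can occur even if both conditions were analyzed jointly;
(2) Welch MS-vs-HC DE on the discovery samples of the condition, B–H
within the iteration, significant at `adj_p <= 0.05`; (3) refit PCA on
the replication half restricted to those proteins; (4) Welch-test PC1
scores between MS and HC replication samples. Per-iteration seeds are
derived deterministically from the master seed, so one integer
reproduces the full run.

Design choices made where the procedure was genuinely open:

* **The PC1 test is a two-sided Welch t-test** — consistent with the
  pipeline's choice for all unequal-variance group comparisons; under
  the null it is calibrated (the suite checks near-uniform p-values on
  permuted labels).
* **PCA is refit on the replication half**, not projected from
  discovery loadings: the validation question is whether the selected
  proteins separate the groups in independent samples, not whether a
  fixed linear combination transfers.
* **Zero-protein iterations** (discovery finds nothing) are recorded
  and counted in the denominator of `proportion_significant` as
  non-significant: dropping them would bias the summary upward exactly
  when the signal is weakest. Under a global null most iterations are
  zero-protein (B–H controls the family-wise chance of any discovery at
  roughly the FDR level), so the null `proportion_significant` sits
  near 0 — well below the nominal 0.05, which is the conservative
  direction.
* **Imputation happens once on the full cohort before resampling**,
  mirroring a pipeline in which validation follows the single processed
  dataset. This is a mild optimism (replication samples informed the
  imputation of discovery samples' missing cells and vice versa), but
  only through column-wise moments, not group labels.

Per-protein *recurrence* — the number of iterations in which a protein
was discovery-significant — identifies the stable core of a signature;
the double-counting identity (recurrence sums equal per-iteration
significant counts summed) is asserted structurally.

# Gene-set enrichment and clinical summaries

Enrichment of activation-responsive proteins in a susceptibility gene
set uses the 2×2 cross-classification of the *analyzed* universe (the
post-filter matrix) by DE membership and gene-set membership,
classified at the protein level (a gene with two protein entries
contributes two counts), with membership by exact uppercase symbol
match; synonym resolution is out of scope and unmatched or absent
symbols count as non-members (their number is attached to the table).
The test is Pearson's chi-squared with 1 df; the Yates continuity
correction is ON by default — on the bundled reference table the
corrected p-value (0.0089) reproduces the behavior of common
statistical software defaults, while the uncorrected statistic gives
≈ 0.006; both routes are pinned in the test suite, and the corrected
p is checked against an exhaustive hypergeometric enumeration on a
small table. The sample odds ratio (ad/bc) is reported for direction.

Clinical summaries report arithmetic means with min–max ranges for age
and disease duration and the median with range for EDSS (an ordinal
0–10 disability scale, where a mean would be misleading). On the
bundled 20-patient table the computed EDSS median is 1.5; the package
always reports the value computed from the per-patient records.

# The synthetic-cohort generator

`generate_cohort()` simulates, on the log2 scale,

```
x[p, d, c] = baseline[p] + donor[d] + activation[p] * stim(c)
             + disease[p, c] * MS(d) + noise
```

with `baseline ~ N(25, 3²)` (log2 units; matching the ~20–31 range of
typical normalized LFQ intensities), `donor ~ N(0, 0.3²)` (induces the
within-donor correlation that makes the paired test more powerful than
an unpaired one), `noise ~ N(0, 0.6²)`, and planted effect magnitudes
drawn from a Gamma(shape 4) with mean `effect_size_log2` (default 1.5)
and random sign — or exactly `effect_size_log2` with
`effect_dist = "fixed"`, used in calibration scenarios where a scenario
is specified as "k proteins at |log2 FC| = e". Default planted
fractions emulate the scale of a real activation study: ~32% of
proteins activation-responsive, ~0.3%/0.6% disease-affected per
condition, ~2.7% contaminants, ~1.7% susceptibility-flagged.
Contaminant rows are ordinary rows carrying a flag and never receive
planted effects.

`inject_missingness()` censors each cell independently with probability
`plogis((20 - x) / 1)` in log2 units — a logistic detection limit
centered about 1.7 baseline SDs below the mean, yielding ~8% missing
cells overall with the steep abundance dependence that makes
downshifted-normal imputation appropriate.

What the generator deliberately does **not** emulate: peptide-level
structure and protein inference, correlated missingness within runs,
batch effects, heavy-tailed or protein-dependent noise variance, and
subpopulation structure among donors. Passing tests on synthetic
cohorts therefore demonstrate the statistical machinery (calibration,
power, invariants), not robustness to every artifact of real LFQ data.

# Problem sizes and numerical tolerances in the test suite

The suite exercises cohorts of 120–1,000 proteins and 20 donors per
group — large enough for stable moments, small enough that the full
suite runs in well under a minute. Calibration checks use 100
resampling iterations (the pipeline default) and, for the null
calibration, 5 master seeds; Monte-Carlo assertions use 3–4 standard
errors of their own sampling distributions as tolerances, and exact
numerical equivalences (PCA reconstruction, orthonormality, oracle
agreement) are asserted at 1e-8.

# Known limitations

* Fold changes are computed post-imputation; proteins with heavy
  censoring in one group inherit the imputation model's assumptions in
  their effect estimates.
* B–H assumes independent or positively dependent tests; protein
  co-regulation violates this mildly, as in all standard LFQ pipelines.
* The enrichment test treats proteins as exchangeable units; paralogous
  proteins of one susceptibility gene count separately.
* No moderated (empirical-Bayes) variance shrinkage is offered; with 20
  donors per group the plain tests are adequately powered, but very
  small cohorts would benefit from moderation this package does not
  provide.
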