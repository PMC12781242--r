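---
title: "Methods: sex-stratified Gini profiles of expression variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified Gini profiles of expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginidimorph)
```

## The statistic

For one gene in one tissue, let `x_1 ... x_n` be the raw TPM values over
the samples of one sex. The Gini coefficient

$$G = \frac{\sum_{i=1}^{n} (2i - n - 1)\, x_{(i)}}{n \sum_i x_i}$$

(sorted values `x_(1) <= ... <= x_(n)`) equals twice the area between the
Lorenz curve and the equality diagonal. We use the population form with no
`n/(n-1)` small-sample correction: cohorts are large (dozens to hundreds of
samples per sex), the uncorrected form is the classical definition, and
stating the choice makes results exactly reproducible. The attainable
maximum is therefore `(n-1)/n`, reached by a one-hot vector.

Three deliberate conventions:

* **Raw TPM, not log TPM.** Log transforms are display conventions here
  (`log2(TPM+1)`, `log10(TPM+1)` in the figures); the statistic itself is
  computed on the TPM scale.
* **Zeros are observations.** Undetectable expression is informative for an
  inequality measure; zeros stay in. A gene that is all-zero (or a
  single-observation vector) has an *undefined* Gini, not 0 — reported as
  `NA` and excluded from downstream Z-score populations.
* **Ties need no special handling**: the sorted-index formula is invariant
  to the permutation of equal values.

`gini_pairwise_oracle()` implements the independent
mean-absolute-difference form
$G = \sum_i\sum_j |x_i - x_j| / (2 n^2 \bar x)$; the test suite holds the
two (and a trapezoid integration of `lorenz_points()`) together within
1e-9 over a thousand random vectors.

## Divergence between the sexes

Per tissue, each gene's difference `d = Gini_M - Gini_F` is standardized
over all genes with a defined difference:
`Z = (d - mean(d)) / sd(d)` with the sample (n−1) standard deviation; if
the standard deviation is zero, all Z are defined as 0 so degenerate
tissues do not crash the stage. The Z population is formed **before** any
TPM or chromosome filtering: the interactive-query semantics let users vary
those filters per query, so the Z column must not depend on them. Queries
then keep genes with `Z >= z_cutoff` (male-direction; `Z <= -z_cutoff` for
the female direction), overall `TPM_mean >= tpm_cutoff`, and chromosome in
the requested class (autosome chr1–22, or chrX/chrY; chrM genes are
excluded from the analysis universe entirely because they belong to neither
query class). Preset cutoffs mirror the usual two-sided normal quantiles —
1.96 (5%) and 2.58 (1%) — and TPM presets 0.1/0.5/1/5/10; defaults are
2.58 and 1.0. Results are ordered by `|Z|` descending with gene-symbol
ties broken alphabetically so outputs are byte-reproducible. No
multiple-testing correction is applied: the Z threshold is the screening
device, and counts should be read as a ranking aid, not as calibrated
discoveries.

## Outlier masking

Single-sample spikes — typically library-preparation or sequencing
artifacts — can push a gene's Gini toward 1 on the strength of one value.
The cleanup stage masks the (gene, sample) value when

1. exactly one sample's pooled-sex Z-score for the gene exceeds 15, and
2. the gene's unweighted mean of male and female Gini exceeds 0.97,

then recomputes means and Gini once (single pass, no re-scan). Reading
notes, since the rule is the least-specified stage of the procedure it
implements:

* the Z-score pools both sexes — the per-sex alternative would change which
  spikes qualify;
* the 0.97 gate applies to the gene's mean of the two per-sex Gini values;
* masking is per value, not per sample: the same donor's other genes and
  tissues stay in the display, consistent with retaining donors whose high
  expression recurs across tissues for biological reasons;
* the gates are surfaced as `outlier_z` / `outlier_gini` arguments so their
  sensitivity can be probed.

A structural consequence worth knowing: with the sample-sd Z-score the
largest attainable value in an n-vector is `(n-1)/sqrt(n)`, so a threshold
of 15 can only ever fire in tissues with at least 232 pooled samples.
Smaller cohorts simply pass through the stage unmasked, which is the
intended conservative behaviour.

## Tissue inclusion and the sample catalog

Of the 54 GTEx V10 per-tissue expression datasets, the pipeline excludes
the two cultured cell lines (matching the spelling variants seen in the
wild), `kidney_medulla` (11 samples), and the eight single-sex reproductive
tissues — the divergence contrast needs both sexes. The remaining 43
tissues total 17,338 samples (11,807 male, 5,531 female); per-tissue
male-to-female ratios, rounded half-up to one decimal for reporting, run
from 1.6 (pancreas) to 3.3 (kidney_cortex) with mean 2.3. Those published
per-tissue counts ship in `inst/extdata/gtex_v10_sample_counts.tsv` so the
catalog arithmetic is testable offline. The gene universe is GENCODE
`protein_coding` intersected with the genes present in each expression
file; MANE Select records decorate gene reports with cross-references but
never filter the universe (its 19,338 records differ from GENCODE's, and
not every gene is expressed in every tissue). Samples whose donor lacks
resolved sex or age are dropped with a warning rather than an error — the
reference procedure silently used only annotated samples, and a hard error
would make whole tissues unusable over a few unannotated donors.

## The simulator: what it emulates and what it does not

`simulate_cohort()` is a test harness, not a model of GTEx. Expression is
log-normal per gene: location uniform on `baseline_log_mean_range`
(default `[0, 4]` natural log, median TPM 1–55, so most genes clear the
default TPM cutoff), dispersion `baseline_sigma = 1` on the log scale —
which yields per-sex Gini values near 0.52, comfortably inside the range
seen in bulk cohorts. Four gene classes with known truth labels:

* **null** — identical dispersion in both sexes;
* **M_variable / F_variable** — sigma multiplied by `dispersion_ratio`
  (default 4) in one sex, directions alternating, `divergent_fraction`
  (default 1%) of genes. At sigma 4 the variable-sex Gini approaches
  `2*pnorm(4/sqrt(2)) - 1 ≈ 0.995`, giving differences near 0.47 against
  per-gene sampling noise of a few hundredths — recoverable but not
  trivially so at the default 200/100 sample sizes;
* **zero** — all-zero (undetectable) genes, default 2%, exercising the
  undefined-Gini paths;
* **sparse** — expressed in exactly two samples per sex (default 1%),
  giving mean Gini ≈ `(n-2)/n > 0.97`. These are the only genes eligible
  for spike injection: a dense log-normal gene can never satisfy the
  0.97 mean-Gini gate, so without a sparse class the outlier stage would
  be untestable end-to-end. Their positive values use a tight log-sd of
  0.1 so that, *without* an injected spike, no natural draw can dominate
  the pooled Z-score past 15.

`inject_spike_outliers()` multiplies one randomly chosen positive value of
`spike_count` eligible genes by `spike_factor` (default 1e4), recording the
(gene, sample) pairs; the outlier stage is required (and tested) to recover
exactly those pairs. Default sample sizes are 200 male / 100 female —
a mid-size tissue with the dominant-male imbalance typical of the catalog
(overall ratio 2.3); ages are uniform over the six decade brackets because
age is display-only downstream. Determinism is part of the contract: the
same `seed` yields bit-identical cohorts, and seeds are confined with
`withr::with_seed` so the caller's RNG state is untouched.

Deliberately not emulated: real marginal TPM distributions, library-size
and batch effects, gene–gene correlation, donor effects shared across
tissues, and X-linked dosage structure (simulated genes are all autosomal;
XY query paths are exercised on hand-built fixtures). Passing tests on
simulated cohorts therefore demonstrate the pipeline's correctness and
calibration under a clean generative model — not that real GTEx tissues
meet those assumptions.

## Numerical and formatting choices

* Undefined statistics propagate as `NA` end-to-end and serialize as `NA`
  in TSV and `null` in JSON (never `NaN`).
* `TPM_mean` is the pooled (count-weighted) mean over unmasked values of
  both sexes; `TPM_mean_M/F` is undefined when the female mean is 0.
* Ratio reporting rounds half away from zero at one decimal, matching the
  published per-tissue M/F ratios.
* Profile TSVs carry the external column names bit-exactly
  (`Gini_index_M-F_Zscore`, `TPM_mean_M/F`, ...), with internal snake_case
  equivalents in memory.
* Gene-record JSON rounds numbers to 6 significant digits;
  export–read–export is idempotent at that precision.
* Figures are deterministic functions of the record (no timestamps, no
  RNG); males are drawn before females, blue/orange, grouped by ascending
  age bracket with lexicographic sample-id tie-break — the within-bracket
  ordering is this package's declared convention.

## Problem sizes in the shipped checks

The test suite validates calibration with 50 replicate null cohorts of
2,000 genes at 200/100 samples (mean fraction of `|Z| >= 2.58` required to
fall in [0.5%, 2%]), recovery with the default divergent configuration
(sensitivity ≥ 0.8 at default cutoffs; in practice recovery is complete),
and exact spike recovery at 300-sample scale — the smallest scale at which
the Z = 15 gate is attainable. Reproducing the per-tissue divergent-gene
counts and per-tissue mean Gini levels of the full GTEx V10 release
requires the multi-gigabyte portal downloads; the README shows the exact
commands, and structural properties (count monotonicity under cutoffs,
Z-population standardization, masking monotonicity, byte-level determinism)
stand in for those stages at desk scale.

## Known limitations

* The Gini difference is compared across genes within a tissue; no
  between-tissue calibration is attempted, so Z-scores are not comparable
  across tissues with very different gene-wise noise.
* Unequal male/female sample sizes bias per-sex Gini estimates slightly
  and differentially; the package reports the uncorrected estimator by
  design.
* The singleton rule masks at most one value per gene and tissue per run;
  coincident double spikes are intentionally left untouched.
* The XY query class groups chrX and chrY; pseudoautosomal regions are not
  distinguished.
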