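# ginidimorph

Sex-stratified Gini-index profiles of gene expression variability across
GTEx tissue cohorts.

Most sex-difference studies compare *average* expression between male and
female cohorts. `ginidimorph` instead asks whether the *variability* of a
protein-coding gene's expression across individuals differs between the
sexes in a given tissue. For each gene *g* in each tissue it computes the
Gini coefficient of the raw TPM values over the male samples and over the
female samples separately,

    G = sum_i (2i - n - 1) * x_(i) / (n * S),     x_(1) <= ... <= x_(n), S = sum(x),

an inequality measure in `[0, (n-1)/n]`: 0 when every individual expresses
the gene identically, approaching 1 when expression is concentrated in a
single sample. The divergence statistic is the difference

    Gini_index_M-F = Gini_M(g) - Gini_F(g)

standardized within each tissue over all genes with a defined difference:

    Z(g) = (d(g) - mean(d)) / sd(d).

Genes with `Z >= 2.58` (or `<= -2.58`, nominal 1% tails) at an overall
expression cutoff (TPM mean >= 1.0 by default) are reported as
sex-divergently variable, split by direction (M > F: more variable in
males) and chromosome class (autosome vs XY).

Because rare single-sample technical spikes can dominate the Gini index,
the pipeline first masks singleton extreme outliers: a gene's value for one
sample is excluded when that sample is the *only* one whose pooled-sex
expression Z-score exceeds 15 and the gene's mean male/female Gini exceeds
0.97; all statistics are then recomputed once on the masked cohort.

## What the package provides

- **Readers/writers** for the standard inputs: per-tissue GCT 1.2 TPM
  matrices (as distributed by the GTEx portal, V10 naming), the GTEx
  subject-phenotypes table, GENCODE GTF (`gene_type = protein_coding`
  selection), and the MANE Select summary (annotation only, never a
  filter); profile tables are written with the exact column names
  `Gini_index_M`, `Gini_index_F`, `Gini_index_M-F`,
  `Gini_index_M-F_Zscore`, `TPM_mean`, `TPM_mean_M`, `TPM_mean_F`,
  `TPM_mean_M/F`.
- **Tissue inclusion rules**: of the 54 GTEx V10 expression datasets, the
  two cultured cell lines, `kidney_medulla`, and the eight single-sex
  reproductive tissues are excluded, leaving the 43 analysis tissues
  (17,338 samples: 11,807 male, 5,531 female; per-tissue M/F ratios from
  1.6 in pancreas to 3.3 in kidney_cortex).
- **Core statistics**: `gini()`, an independent `gini_pairwise_oracle()`,
  `lorenz_points()`, `zscores()`, `two_sided_tail()`.
- **Outlier stage**: `find_extreme_singletons()` / `apply_exclusions()`.
- **Profiles and queries**: `compute_profiles()`, `divergence_zscores()`,
  `query_divergent()`, `count_divergent()`.
- **Simulator**: `sim_config()` / `simulate_cohort()` generate GTEx-like
  log-normal cohorts with known ground truth (sex-specific dispersion,
  all-zero genes, sparse near-one-Gini genes, injectable spikes) so every
  stage is testable without downloading GTEx.
- **Reporting**: per-gene records (`gene_record()`, JSON export) and
  figures (per-sample scatter colored by sex and grouped by age bracket;
  cross-tissue male/female bars for Gini and TPM mean).
- **Pipeline entry points** `pipeline_profile()`, `pipeline_query()`,
  `pipeline_simulate()` plus a thin CLI at `inst/cli/ginidimorph`
  (subcommands `profile`, `query`, `simulate`, `plot`).

## Worked example

Simulate a mid-size tissue cohort (2,000 genes, 200 male / 100 female
samples) in which 1% of genes have a four-fold dispersion ratio in one sex,
then query for male-variable genes at the default cutoffs:

```r
library(ginidimorph)

cfg <- sim_config(n_genes = 2000, n_male = 200, n_female = 100,
                  divergent_fraction = 0.01, dispersion_ratio = 4, seed = 11)
sim <- simulate_cohort(cfg, tissue_name = "liver")
profiles <- divergence_zscores(compute_profiles(sim$cohort))
res <- query_divergent(profiles,
                       divergence_query(2.58, 1.0, "autosome", "M_greater"))
res
#> <divergence_result> liver: 10 gene(s) at Z >= 2.58, TPM >= 1, autosome
head(res$genes[, c("gene_symbol", "gini_M", "gini_F", "gini_diff",
                   "gini_diff_z", "tpm_mean")], 5)
#>   gene_symbol    gini_M    gini_F gini_diff gini_diff_z   tpm_mean
#> 1     SIM1286 0.9895672 0.4823998 0.5071674    7.610959 22841.0668
#> 2     SIM0533 0.9733161 0.4823573 0.4909588    7.365377   498.8381
#> 3     SIM1328 0.9632587 0.5134901 0.4497686    6.741293  5027.3783
#> 4     SIM1703 0.9534722 0.5047271 0.4487451    6.725785 10228.2738
#> 5     SIM1342 0.9597815 0.5201780 0.4396035    6.587279  5013.7910
```

All ten genes reported here are exactly the ten simulated as
male-variable: their male Gini sits near 0.96–0.99 (four-fold log-scale
dispersion concentrates expression in few samples) against a female Gini
near 0.5 (the σ = 1 log-normal baseline), and the within-tissue Z-scores
of those differences are far beyond the 2.58 cutoff.

Running against real GTEx V10 data is the same flow on downloaded inputs
(~GBs, not shipped):

```sh
Rscript inst/cli/ginidimorph profile \
  --input-dir gtex_v10_gct/ \
  --phenotypes GTEx_Analysis_v10_Annotations_SubjectPhenotypesDS.txt \
  --gtf gencode.v39.annotation.gtf \
  --mane MANE.GRCh38.v1.4.summary.txt \
  --output-dir profiles/
Rscript inst/cli/ginidimorph query --profile profiles/liver.profiles.tsv \
  --z-cutoff 2.58 --tpm-cutoff 1.0 --direction M_greater
```

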