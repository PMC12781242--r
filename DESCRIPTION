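Package: ginidimorph
Title: Sex-Stratified Gini-Index Profiles of Gene Expression Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sex-stratified Gini-index profiles of protein-coding
    gene expression variability across GTEx-style tissue cohorts. Reads
    per-tissue TPM matrices (GCT 1.2), GTEx subject phenotypes, GENCODE
    gene annotation and MANE Select summaries; applies the tissue
    inclusion rules and singleton extreme-outlier exclusion; computes
    per-gene male and female Gini coefficients, their difference and its
    per-tissue Z-score; supports divergence queries at preset Z and TPM
    cutoffs; and renders per-gene, per-sample visualization artifacts.
    Includes a log-normal cohort simulator with known ground truth for
    end-to-end validation without GTEx downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
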