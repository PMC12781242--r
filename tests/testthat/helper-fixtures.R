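# In-code fixtures shared across test files. Everything is generated at test
# time; no binary data ships with the package.

# Minimal protein-coding annotation table.
toy_annotations <- function(gene_ids, chromosome = NULL, symbols = NULL) {
  n <- length(gene_ids)
  data.frame(
    gene_id = strip_ver(gene_ids),
    gene_id_version = gene_ids,
    gene_symbol = symbols %||na% sprintf("SYM%02d", seq_len(n)),
    chromosome = chromosome %||na% rep("chr1", n),
    gene_type = "protein_coding",
    stringsAsFactors = FALSE
  )
}

`%||na%` <- function(a, b) if (is.null(a)) b else a
strip_ver <- function(x) sub("\\.[0-9]+$", "", x)

toy_phenotypes <- function(donors, sex, age = NULL) {
  data.frame(
    donor_id = donors,
    sex = sex,
    age_bracket = age %||na% rep("40", length(donors)),
    stringsAsFactors = FALSE
  )
}

# Build a tissue_cohort from a values matrix via the public constructor
# chain (expression_matrix -> build_cohort), one donor per sample.
toy_cohort <- function(values, sexes, tissue = "toy_tissue",
                       chromosome = NULL, ages = NULL) {
  n_genes <- nrow(values)
  n_samples <- ncol(values)
  stopifnot(length(sexes) == n_samples)
  gene_ids <- sprintf("ENSG%08d.1", seq_len(n_genes))
  donors <- sprintf("TOYD-%04d", seq_len(n_samples))
  sample_ids <- paste0(donors, "-0001-SM-X")
  em <- expression_matrix(tissue, gene_ids,
                          sprintf("SYM%02d", seq_len(n_genes)),
                          sample_ids, values)
  build_cohort(em, toy_phenotypes(donors, sexes, ages),
               toy_annotations(gene_ids, chromosome))
}

# A 300-sample cohort (150M/150F) holding one near-one-Gini sparse gene, one
# dense log-normal gene, and an optional extra sparse gene; used by the
# outlier tests. Spikes are applied by the caller.
sparse_spike_cohort <- function(n_per_sex = 150, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_sex
    sparse1 <- rep(0, n)
    sparse1[c(1, 2, n_per_sex + 1, n_per_sex + 2)] <- 10
    sparse2 <- rep(0, n)
    sparse2[c(3, 4, n_per_sex + 3, n_per_sex + 4)] <- 8
    dense <- rlnorm(n, meanlog = 2, sdlog = 1)
    values <- rbind(sparse1, sparse2, dense)
    rownames(values) <- NULL
    toy_cohort(values, rep(c("male", "female"), each = n_per_sex))
  })
}

write_text <- function(lines, path) {
  writeLines(lines, path)
  path
}
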