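# Synthetic GTEx-like cohorts with known ground truth.
#
# Expression is drawn log-normally per gene: log TPM location uniform over
# `baseline_log_mean_range`, dispersion `baseline_sigma` on the log scale.
# A `divergent_fraction` of genes gets sex-specific dispersion (sigma
# multiplied by `dispersion_ratio` in the variable sex, direction assigned
# alternately male/female). A `zero_gene_fraction` of genes is emitted
# all-zero (undetectable in the tissue). A `sparse_gene_fraction` of genes
# is expressed in only two samples per sex — the near-one-Gini regime in
# which rare single-sample technical spikes are detectable; their positive
# values use a tight dispersion (sigma 0.1) so that, without an injected
# spike, no natural singleton can dominate the pooled Z-score.

#' Simulation configuration
#'
#' @param n_genes number of genes (default 2000).
#' @param n_male,n_female sample counts (defaults 200 and 100, the scale of
#'   a mid-size GTEx tissue).
#' @param baseline_log_mean_range interval for the per-gene natural-log TPM
#'   location (default `c(0, 4)`, i.e. median TPM 1 to ~55).
#' @param baseline_sigma log-scale dispersion of null genes (default 1).
#' @param divergent_fraction proportion of genes with sex-specific
#'   dispersion (default 0.01).
#' @param dispersion_ratio sigma multiplier in the variable sex (default 4;
#'   must be >= 1).
#' @param zero_gene_fraction proportion of all-zero genes (default 0.02).
#' @param sparse_gene_fraction proportion of two-samples-per-sex genes
#'   (default 0.01).
#' @param spike_count number of single-sample extreme spikes to inject via
#'   [inject_spike_outliers()] (default 0).
#' @param spike_factor multiplier applied to the spiked value (default 1e4).
#' @param seed integer RNG seed; the same seed yields bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_male = 200L, n_female = 100L,
                       baseline_log_mean_range = c(0, 4),
                       baseline_sigma = 1,
                       divergent_fraction = 0.01,
                       dispersion_ratio = 4,
                       zero_gene_fraction = 0.02,
                       sparse_gene_fraction = 0.01,
                       spike_count = 0L,
                       spike_factor = 1e4,
                       seed = 1L) {
  frac <- c(divergent_fraction, zero_gene_fraction, sparse_gene_fraction)
  ok <- n_genes >= 1L && n_male >= 0L && n_female >= 0L &&
    length(baseline_log_mean_range) == 2L &&
    baseline_log_mean_range[1] <= baseline_log_mean_range[2] &&
    baseline_sigma > 0 &&
    all(frac >= 0 & frac <= 1) && sum(frac) <= 1 &&
    dispersion_ratio >= 1 &&
    spike_count >= 0L && spike_count <= n_genes && spike_factor > 0
  if (!ok) {
    gd_abort("invalid simulation configuration", "gd_domain_error")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_male = as.integer(n_male),
         n_female = as.integer(n_female),
         baseline_log_mean_range = as.numeric(baseline_log_mean_range),
         baseline_sigma = baseline_sigma,
         divergent_fraction = divergent_fraction,
         dispersion_ratio = dispersion_ratio,
         zero_gene_fraction = zero_gene_fraction,
         sparse_gene_fraction = sparse_gene_fraction,
         spike_count = as.integer(spike_count), spike_factor = spike_factor,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

SPARSE_PER_SEX <- 2L     # positive samples per sex in a sparse gene
SPARSE_SIGMA <- 0.1      # log-sd among a sparse gene's positive values

#' Simulate a GTEx-like tissue cohort with known ground truth
#'
#' @param config a [sim_config()].
#' @param tissue_name tissue label for the simulated cohort.
#' @return List with elements `cohort` (a `tissue_cohort`) and `truth`
#'   (`data.frame` with `gene_id` and `class` in
#'   `null`/`M_variable`/`F_variable`/`zero`/`sparse`).
#' @export
simulate_cohort <- function(config, tissue_name = "sim_tissue") {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  n_samples <- config$n_male + config$n_female
  withr::with_seed(config$seed, {
    gene_num <- seq_len(n_genes)
    gene_id <- sprintf("ENSG9%010d", gene_num)
    gene_symbol <- sprintf("SIM%04d", gene_num)

    n_zero <- round(config$zero_gene_fraction * n_genes)
    n_sparse <- round(config$sparse_gene_fraction * n_genes)
    n_div <- round(config$divergent_fraction * n_genes)
    shuffled <- sample(gene_num)
    class <- rep("null", n_genes)
    class[shuffled[seq_len(n_zero)]] <- "zero"
    class[shuffled[n_zero + seq_len(n_sparse)]] <- "sparse"
    div_idx <- shuffled[n_zero + n_sparse + seq_len(n_div)]
    if (n_div > 0L) {
      class[div_idx] <- rep_len(c("M_variable", "F_variable"), n_div)
    }

    mu <- stats::runif(n_genes, config$baseline_log_mean_range[1],
                       config$baseline_log_mean_range[2])
    sex <- rep(c("male", "female"), c(config$n_male, config$n_female))
    male <- sex == "male"

    values <- matrix(0, nrow = n_genes, ncol = n_samples)
    for (i in gene_num) {
      cls <- class[i]
      if (cls == "zero") next
      if (cls == "sparse") {
        pick_m <- sample(which(male), min(SPARSE_PER_SEX, config$n_male))
        pick_f <- sample(which(!male), min(SPARSE_PER_SEX, config$n_female))
        pick <- c(pick_m, pick_f)
        values[i, pick] <- stats::rlnorm(length(pick), mu[i], SPARSE_SIGMA)
        next
      }
      sig_m <- config$baseline_sigma
      sig_f <- config$baseline_sigma
      if (cls == "M_variable") sig_m <- sig_m * config$dispersion_ratio
      if (cls == "F_variable") sig_f <- sig_f * config$dispersion_ratio
      values[i, male] <- stats::rlnorm(config$n_male, mu[i], sig_m)
      values[i, !male] <- stats::rlnorm(config$n_female, mu[i], sig_f)
    }

    donor_id <- sprintf("SIMD-%04d", seq_len(n_samples))
    sample_id <- sprintf("%s-0826-SM-%04d", donor_id, seq_len(n_samples))
    age_bracket <- sample(AGE_BRACKETS, n_samples, replace = TRUE)

    genes <- data.frame(
      gene_id = gene_id,
      gene_id_version = paste0(gene_id, ".1"),
      gene_symbol = gene_symbol,
      chromosome = paste0("chr", (gene_num - 1L) %% 22L + 1L),
      gene_type = "protein_coding",
      stringsAsFactors = FALSE
    )
    samples <- data.frame(
      sample_id = sample_id, donor_id = donor_id, sex = sex,
      age_bracket = age_bracket, stringsAsFactors = FALSE
    )
    dimnames(values) <- list(gene_id, sample_id)
    cohort <- structure(
      list(tissue_name = tissue_name, genes = genes, samples = samples,
           values = values,
           mask = matrix(FALSE, n_genes, n_samples,
                         dimnames = dimnames(values)),
           n_male = config$n_male, n_female = config$n_female),
      class = "tissue_cohort"
    )
    truth <- data.frame(gene_id = gene_id, class = class,
                        log_mean = mu, stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}

#' Inject single-sample extreme spikes into a simulated cohort
#'
#' Picks `spike_count` distinct high-Gini-eligible genes — genes whose
#' current mean male/female Gini already exceeds the outlier gate and that
#' have at least one positive value — and multiplies one randomly chosen
#' positive sample value per gene by `spike_factor`, emulating a technical
#' artifact. The injected (gene, sample) pairs are returned so recovery by
#' [find_extreme_singletons()] can be checked exactly.
#'
#' @param cohort a `tissue_cohort` (typically from [simulate_cohort()]).
#' @param config the [sim_config()] carrying `spike_count`, `spike_factor`
#'   and `seed`.
#' @param gini_threshold eligibility gate on the gene's mean male/female
#'   Gini (default 0.97, matching the outlier stage).
#' @return List with elements `cohort` (spiked) and `injected`
#'   (`data.frame` with `gene_id`, `sample_id`, `original`, `spiked`).
#' @export
inject_spike_outliers <- function(cohort, config, gini_threshold = 0.97) {
  stopifnot(inherits(cohort, "tissue_cohort"), inherits(config, "sim_config"))
  injected <- data.frame(gene_id = character(), sample_id = character(),
                         original = numeric(), spiked = numeric(),
                         stringsAsFactors = FALSE)
  if (config$spike_count == 0L) {
    return(list(cohort = cohort, injected = injected))
  }
  male <- cohort$samples$sex == "male"
  gm <- row_gini(cohort$values[, male, drop = FALSE])
  gf <- row_gini(cohort$values[, !male, drop = FALSE])
  eligible <- which(!is.na(gm) & !is.na(gf) &
                      (gm + gf) / 2 > gini_threshold &
                      rowSums(cohort$values > 0) > 0)
  if (length(eligible) < config$spike_count) {
    gd_abort(sprintf(
      "only %d high-Gini-eligible gene(s) available for %d spike(s)",
      length(eligible), config$spike_count), "gd_domain_error")
  }
  withr::with_seed(config$seed + 1L, {
    targets <- sample(eligible, config$spike_count)
    rows <- lapply(targets, function(i) {
      positive <- which(cohort$values[i, ] > 0)
      j <- if (length(positive) == 1L) positive else sample(positive, 1L)
      orig <- cohort$values[i, j]
      data.frame(gene_id = cohort$genes$gene_id[i],
                 sample_id = cohort$samples$sample_id[j],
                 original = orig, spiked = orig * config$spike_factor,
                 stringsAsFactors = FALSE)
    })
    injected <- do.call(rbind, rows)
  })
  gi <- match(injected$gene_id, cohort$genes$gene_id)
  si <- match(injected$sample_id, cohort$samples$sample_id)
  cohort$values[cbind(gi, si)] <- injected$spiked
  rownames(injected) <- NULL
  list(cohort = cohort, injected = injected)
}

#' Write a simulated cohort as pipeline-ready fixture files
#'
#' Materializes the cohort as the same file set the readers consume: a GCT
#' 1.2 expression matrix, a subject-phenotype TSV (numeric sex codes,
#' `"20-29"`-style age brackets), a minimal GENCODE-dialect GTF restricted
#' to gene records, and a MANE-style summary TSV with MANE Select rows.
#' Reading these back and rebuilding the cohort reproduces it.
#'
#' @param cohort a `tissue_cohort`.
#' @param directory output directory (created if needed).
#' @param mane_fraction fraction of genes given a MANE Select record
#'   (default 1).
#' @return Named list of the written paths (`gct`, `phenotypes`, `gtf`,
#'   `mane`), invisibly.
#' @export
write_fixture_files <- function(cohort, directory, mane_fraction = 1) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gct = file.path(directory, paste0(cohort$tissue_name, ".gct")),
    phenotypes = file.path(directory, "subject_phenotypes.tsv"),
    gtf = file.path(directory, "annotation.gtf"),
    mane = file.path(directory, "mane_summary.tsv")
  )

  em <- expression_matrix(cohort$tissue_name, cohort$genes$gene_id_version,
                          cohort$genes$gene_symbol, cohort$samples$sample_id,
                          cohort$values)
  write_gct(em, paths$gct)

  bracket_to_age <- c("20" = "20-29", "30" = "30-39", "40" = "40-49",
                      "50" = "50-59", "60" = "60-69", "70+" = "70-79")
  pheno <- data.frame(
    SUBJID = cohort$samples$donor_id,
    SEX = ifelse(cohort$samples$sex == "male", 1L, 2L),
    AGE = unname(bracket_to_age[cohort$samples$age_bracket]),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(pheno, paths$phenotypes, sep = "\t", quote = FALSE)

  gtf_lines <- sprintf(
    '%s\tSIMULATED\tgene\t1\t1000\t.\t+\t.\tgene_id "%s"; gene_type "%s"; gene_name "%s";',
    cohort$genes$chromosome, cohort$genes$gene_id_version,
    cohort$genes$gene_type, cohort$genes$gene_symbol)
  writeLines(gtf_lines, paths$gtf)

  n_mane <- round(mane_fraction * nrow(cohort$genes))
  mane_rows <- utils::head(cohort$genes, n_mane)
  mane <- data.frame(
    "#NCBI_GeneID" = paste0("GeneID:", seq_len(nrow(mane_rows))),
    Ensembl_Gene = mane_rows$gene_id_version,
    HGNC_ID = paste0("HGNC:", seq_len(nrow(mane_rows))),
    symbol = mane_rows$gene_symbol,
    name = paste("simulated gene", mane_rows$gene_symbol),
    RefSeq_nuc = sprintf("NM_%06d.1", seq_len(nrow(mane_rows))),
    RefSeq_prot = sprintf("NP_%06d.1", seq_len(nrow(mane_rows))),
    Ensembl_nuc = sub("ENSG", "ENST", mane_rows$gene_id_version),
    Ensembl_prot = sub("ENSG", "ENSP", mane_rows$gene_id_version),
    MANE_status = "MANE Select",
    GRCh38_chr = mane_rows$chromosome,
    chr_start = 1L, chr_end = 1000L, chr_strand = "+",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  data.table::fwrite(mane, paths$mane, sep = "\t", quote = FALSE)

  invisible(paths)
}
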