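# Sex-stratified per-gene profiles, divergence Z-scores, and the query and
# count layer over them.

AUTOSOMES <- paste0("chr", 1:22)
SEX_CHROMOSOMES <- c("chrX", "chrY")

#' Compute sex-stratified expression profiles for one tissue
#'
#' Per gene: the Gini index over male samples, over female samples, their
#' difference (`gini_diff = gini_M - gini_F`), and arithmetic TPM means
#' overall and per sex. Masked (outlier-excluded) values are removed from
#' both the numerator and the observation count. The male/female mean ratio
#' is undefined when the female mean is zero. The divergence Z-score column
#' is initialized to `NA` and filled by [divergence_zscores()].
#'
#' @param cohort a (possibly masked) [build_cohort()] result with both
#'   sexes.
#' @return `data.frame` with one row per gene and columns `gene_id`,
#'   `gene_symbol`, `chromosome`, `tissue`, `n_M`, `n_F`, `gini_M`,
#'   `gini_F`, `gini_diff`, `gini_diff_z`, `tpm_mean`, `tpm_mean_M`,
#'   `tpm_mean_F`, `tpm_ratio_MF`.
#' @export
compute_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  if (cohort$n_male == 0L || cohort$n_female == 0L) {
    gd_abort(sprintf("cohort %s lacks one sex; cannot stratify",
                     cohort$tissue_name), "gd_cohort_error")
  }
  male <- cohort$samples$sex == "male"
  n_genes <- nrow(cohort$values)

  gini_M <- gini_F <- tpm_mean <- tpm_mean_M <- tpm_mean_F <-
    rep(NA_real_, n_genes)
  n_M <- n_F <- rep(NA_integer_, n_genes)
  for (i in seq_len(n_genes)) {
    keep <- !cohort$mask[i, ]
    vm <- cohort$values[i, male & keep]
    vf <- cohort$values[i, !male & keep]
    gini_M[i] <- gini(vm)
    gini_F[i] <- gini(vf)
    n_M[i] <- length(vm)
    n_F[i] <- length(vf)
    tpm_mean_M[i] <- if (length(vm)) mean(vm) else NA_real_
    tpm_mean_F[i] <- if (length(vf)) mean(vf) else NA_real_
    tpm_mean[i] <- mean(c(vm, vf))
  }
  gini_diff <- gini_M - gini_F
  tpm_ratio_MF <- ifelse(!is.na(tpm_mean_F) & tpm_mean_F > 0,
                         tpm_mean_M / tpm_mean_F, NA_real_)
  data.frame(
    gene_id = cohort$genes$gene_id,
    gene_symbol = cohort$genes$gene_symbol,
    chromosome = cohort$genes$chromosome,
    tissue = cohort$tissue_name,
    n_M = n_M,
    n_F = n_F,
    gini_M = gini_M,
    gini_F = gini_F,
    gini_diff = gini_diff,
    gini_diff_z = NA_real_,
    tpm_mean = tpm_mean,
    tpm_mean_M = tpm_mean_M,
    tpm_mean_F = tpm_mean_F,
    tpm_ratio_MF = tpm_ratio_MF,
    stringsAsFactors = FALSE
  )
}

#' Fill divergence Z-scores for one tissue's profiles
#'
#' Z-scores the Gini difference over the population of all genes in the
#' tissue whose difference is defined — before any TPM or chromosome
#' filtering, so the Z column is independent of later query filters. Genes
#' with undefined differences keep an undefined Z.
#'
#' @param profiles a single-tissue [compute_profiles()] result.
#' @return The same `data.frame` with `gini_diff_z` filled.
#' @export
divergence_zscores <- function(profiles) {
  if (length(unique(profiles$tissue)) > 1L) {
    gd_abort("divergence Z-scores are per-tissue; got multiple tissues",
             "gd_contract_error")
  }
  defined <- !is.na(profiles$gini_diff)
  if (sum(defined) < 2L) {
    gd_abort("fewer than 2 genes with defined Gini differences",
             "gd_domain_error")
  }
  profiles$gini_diff_z <- NA_real_
  profiles$gini_diff_z[defined] <- zscores(profiles$gini_diff[defined])
  profiles
}

#' Construct a divergence query
#'
#' Presets mirror the interactive query page: Z cutoffs 1.96 (5%) or 2.58
#' (1%); overall TPM cutoffs 0.1, 0.5, 1.0, 5, 10; autosome (chr1-22) or XY
#' chromosome class; and the direction of the Gini difference (`M_greater`:
#' more variable in males). Other positive cutoffs are permitted.
#'
#' @param z_cutoff positive Z-score threshold (default 2.58).
#' @param tpm_cutoff nonnegative overall-TPM threshold (default 1.0).
#' @param chrom_class `"autosome"` or `"XY"`.
#' @param direction `"M_greater"` or `"F_greater"`.
#' @return An object of class `divergence_query`.
#' @export
divergence_query <- function(z_cutoff = 2.58, tpm_cutoff = 1.0,
                             chrom_class = c("autosome", "XY"),
                             direction = c("M_greater", "F_greater")) {
  chrom_class <- match.arg(chrom_class)
  direction <- match.arg(direction)
  if (!is.numeric(z_cutoff) || length(z_cutoff) != 1L || z_cutoff <= 0) {
    gd_abort("z_cutoff must be a single positive number", "gd_domain_error")
  }
  if (!is.numeric(tpm_cutoff) || length(tpm_cutoff) != 1L || tpm_cutoff < 0) {
    gd_abort("tpm_cutoff must be a single nonnegative number",
             "gd_domain_error")
  }
  structure(list(z_cutoff = z_cutoff, tpm_cutoff = tpm_cutoff,
                 chrom_class = chrom_class, direction = direction),
            class = "divergence_query")
}

#' Select sex-divergently-variable genes in one tissue
#'
#' Keeps genes whose divergence Z-score passes the directional cutoff
#' (`M_greater`: `Z >= z_cutoff`; `F_greater`: `Z <= -z_cutoff`), whose
#' overall TPM mean passes the expression cutoff, and whose chromosome is in
#' the requested class. Results are ordered by `|Z|` descending with ties
#' broken by gene symbol ascending, so output is byte-reproducible.
#'
#' @param profiles a scored single-tissue profile table (after
#'   [divergence_zscores()]).
#' @param query a [divergence_query()].
#' @return An object of class `divergence_result`: list with `tissue_name`,
#'   `query`, `genes` (the selected profile rows, ordered) and `count`.
#' @export
query_divergent <- function(profiles, query = divergence_query()) {
  stopifnot(inherits(query, "divergence_query"))
  chroms <- if (query$chrom_class == "autosome") AUTOSOMES else
    SEX_CHROMOSOMES
  z <- profiles$gini_diff_z
  pass_z <- if (query$direction == "M_greater") {
    !is.na(z) & z >= query$z_cutoff
  } else {
    !is.na(z) & z <= -query$z_cutoff
  }
  keep <- pass_z &
    !is.na(profiles$tpm_mean) & profiles$tpm_mean >= query$tpm_cutoff &
    profiles$chromosome %in% chroms
  genes <- profiles[keep, , drop = FALSE]
  ord <- order(-abs(genes$gini_diff_z), genes$gene_symbol)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(
      tissue_name = if (nrow(profiles)) unique(profiles$tissue)[1] else
        NA_character_,
      query = query,
      genes = genes,
      count = nrow(genes)
    ),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "<divergence_result> %s: %d gene(s) at Z %s %.2f, TPM >= %g, %s\n",
    x$tissue_name, x$count,
    if (x$query$direction == "M_greater") ">=" else "<= -",
    x$query$z_cutoff, x$query$tpm_cutoff, x$query$chrom_class))
  invisible(x)
}

#' Count divergently variable autosomal genes per tissue
#'
#' Applies [query_divergent()] in both directions with the autosome
#' chromosome class across tissues, yielding a per-tissue summary of
#' male-variable (M > F) and female-variable (M < F) gene counts.
#'
#' @param profiles_list named list of scored per-tissue profile tables.
#' @param z_cutoff,tpm_cutoff thresholds (defaults 2.58 and 1.0).
#' @return `data.frame` with columns `tissue`, `n_M_greater`,
#'   `n_F_greater`.
#' @export
count_divergent <- function(profiles_list, z_cutoff = 2.58,
                            tpm_cutoff = 1.0) {
  if (!length(profiles_list)) {
    return(data.frame(tissue = character(), n_M_greater = integer(),
                      n_F_greater = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(profiles_list, function(p) {
    data.frame(
      tissue = unique(p$tissue)[1],
      n_M_greater = query_divergent(p, divergence_query(
        z_cutoff, tpm_cutoff, "autosome", "M_greater"))$count,
      n_F_greater = query_divergent(p, divergence_query(
        z_cutoff, tpm_cutoff, "autosome", "F_greater"))$count,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
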