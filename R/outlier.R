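# Singleton extreme-outlier exclusion.
#
# Rare single-sample expression spikes (typically NGS technical artifacts)
# can dominate a gene's Gini index. A gene's value for one sample is masked
# when (a) that sample is the only one in the tissue whose pooled-sex
# expression Z-score exceeds `z_threshold` (default 15) and (b) the
# unweighted mean of the gene's male and female Gini indices exceeds
# `gini_threshold` (default 0.97). Statistics are then recomputed once on
# the masked cohort; there is no iterative re-scan.

#' Find singleton extreme-outlier values
#'
#' Per gene, Z-scores are computed over all samples of the tissue (both
#' sexes pooled, raw TPM, unmasked values). A record is emitted iff exactly
#' one sample exceeds the Z threshold for that gene and the mean of the
#' gene's male and female Gini indices exceeds the Gini gate, so at most one
#' record per gene and tissue.
#'
#' Note the sample-sd Z-score bounds attainable values at
#' \eqn{(n-1)/\sqrt{n}}: with the default threshold of 15 the gate can only
#' open in tissues with at least 232 pooled samples.
#'
#' @param cohort an unmasked [build_cohort()] result.
#' @param gini_m,gini_f optional precomputed per-gene Gini vectors (male and
#'   female columns respectively), aligned to `cohort$genes`; computed from
#'   the cohort when omitted.
#' @param z_threshold singleton Z-score gate (default 15).
#' @param gini_threshold mean-Gini gate (default 0.97).
#' @return `data.frame` with columns `tissue`, `gene_id`, `sample_id`,
#'   `zscore`, `mean_gini_before` (zero rows when nothing qualifies).
#' @export
find_extreme_singletons <- function(cohort, gini_m = NULL, gini_f = NULL,
                                    z_threshold = 15, gini_threshold = 0.97) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  male <- cohort$samples$sex == "male"
  if (is.null(gini_m)) {
    gini_m <- row_gini(cohort$values[, male, drop = FALSE])
  }
  if (is.null(gini_f)) {
    gini_f <- row_gini(cohort$values[, !male, drop = FALSE])
  }
  empty <- data.frame(tissue = character(), gene_id = character(),
                      sample_id = character(), zscore = numeric(),
                      mean_gini_before = numeric(), stringsAsFactors = FALSE)
  n_genes <- nrow(cohort$values)
  if (!n_genes || ncol(cohort$values) < 2L) {
    return(empty)
  }
  records <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    mg <- (gini_m[i] + gini_f[i]) / 2
    if (is.na(mg) || mg <= gini_threshold) next
    v <- cohort$values[i, ]
    if (stats::sd(v) == 0) next
    z <- zscores(v)
    hit <- which(z > z_threshold)
    if (length(hit) != 1L) next
    records[[i]] <- data.frame(
      tissue = cohort$tissue_name,
      gene_id = cohort$genes$gene_id[i],
      sample_id = cohort$samples$sample_id[hit],
      zscore = z[hit],
      mean_gini_before = mg,
      stringsAsFactors = FALSE
    )
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (!length(records)) {
    return(empty)
  }
  do.call(rbind, records)
}

#' Mask singleton outlier values in a cohort
#'
#' Masks exactly the (gene, sample) values named in `records`; every other
#' value — including the same sample's values for other genes — is
#' untouched. Downstream means and Gini indices for a masked gene use one
#' fewer observation in the affected sex. Masking is single-pass: the masked
#' cohort is not re-scanned for new outliers.
#'
#' @param cohort a [build_cohort()] result.
#' @param records output of [find_extreme_singletons()] on this cohort.
#' @return The cohort with its mask updated.
#' @export
apply_exclusions <- function(cohort, records) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  if (!nrow(records)) {
    return(cohort)
  }
  gi <- match(records$gene_id, cohort$genes$gene_id)
  si <- match(records$sample_id, cohort$samples$sample_id)
  if (anyNA(gi) || anyNA(si)) {
    gd_abort("exclusion record references a gene or sample not in the cohort",
             "gd_contract_error")
  }
  cohort$mask[cbind(gi, si)] <- TRUE
  cohort
}

#' Write the exclusion log
#'
#' @param records output of [find_extreme_singletons()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(records, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
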