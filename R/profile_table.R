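# Tabular output of per-gene, per-tissue profiles: the table-view columns of
# the query interface, written with bit-exact column names.

PROFILE_TABLE_COLUMNS <- c(
  gene_id = "gene_id",
  gene_symbol = "gene_symbol",
  chromosome = "chromosome",
  tissue = "tissue",
  n_M = "n_M",
  n_F = "n_F",
  gini_M = "Gini_index_M",
  gini_F = "Gini_index_F",
  gini_diff = "Gini_index_M-F",
  gini_diff_z = "Gini_index_M-F_Zscore",
  tpm_mean = "TPM_mean",
  tpm_mean_M = "TPM_mean_M",
  tpm_mean_F = "TPM_mean_F",
  tpm_ratio_MF = "TPM_mean_M/F"
)

#' Write a per-tissue profile table
#'
#' Tab-separated, one row per gene, with the external column names
#' `Gini_index_M`, `Gini_index_F`, `Gini_index_M-F`,
#' `Gini_index_M-F_Zscore`, `TPM_mean`, `TPM_mean_M`, `TPM_mean_F`,
#' `TPM_mean_M/F` plus gene identity columns. Undefined statistics (e.g. the
#' Gini of an all-zero gene) are written as `NA`.
#'
#' @param profiles a profile `data.frame` as produced by
#'   [compute_profiles()]; all rows must belong to one tissue.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  internal <- names(PROFILE_TABLE_COLUMNS)
  missing <- setdiff(internal, names(profiles))
  if (length(missing)) {
    gd_abort(sprintf("profile table lacks column(s): %s",
                     paste(missing, collapse = ", ")), "gd_contract_error")
  }
  if (length(unique(profiles$tissue)) > 1L) {
    gd_abort("profiles mix multiple tissues; write one table per tissue",
             "gd_contract_error")
  }
  out <- profiles[, internal, drop = FALSE]
  names(out) <- unname(PROFILE_TABLE_COLUMNS)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a profile table written by [write_profile_table()]
#'
#' @param path path to the TSV.
#' @return Profile `data.frame` with internal column names, round-tripping
#'   [write_profile_table()] output.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) {
    gd_abort(sprintf("profile table not found: %s", path), "gd_io_error")
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE,
                           na.strings = "NA")
  missing <- setdiff(unname(PROFILE_TABLE_COLUMNS), names(tab))
  if (length(missing)) {
    gd_abort(sprintf("profile table %s lacks column(s): %s", path,
                     paste(missing, collapse = ", ")), "gd_format_error")
  }
  tab <- tab[, unname(PROFILE_TABLE_COLUMNS), drop = FALSE]
  names(tab) <- names(PROFILE_TABLE_COLUMNS)
  for (nm in c("gini_M", "gini_F", "gini_diff", "gini_diff_z", "tpm_mean",
               "tpm_mean_M", "tpm_mean_F", "tpm_ratio_MF")) {
    tab[[nm]] <- as.numeric(tab[[nm]])
  }
  for (nm in c("n_M", "n_F")) tab[[nm]] <- as.integer(tab[[nm]])
  tab
}
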