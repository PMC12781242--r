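# Per-gene reporting artifacts: the machine-readable gene record, the
# per-sample scatter for a focal tissue, and cross-tissue male/female bars.

#' Assemble a per-gene record
#'
#' The full content of a gene's report page: its annotation, one profile row
#' per analyzed tissue, and the per-sample expression values for a focal
#' tissue.
#'
#' @param annotation single-row gene annotation `data.frame` (at least
#'   `gene_id`, `gene_symbol`, `chromosome`; MANE cross-reference columns
#'   are carried through when present).
#' @param per_tissue profile `data.frame` (profile-table columns) covering
#'   every analyzed tissue exactly once for this gene.
#' @param focal_tissue tissue whose samples are shown; must appear in
#'   `per_tissue`.
#' @param samples `data.frame` with columns `sample_id`, `sex`,
#'   `age_bracket`, `tpm` for the focal tissue.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(annotation, per_tissue, focal_tissue, samples) {
  if (!is.data.frame(per_tissue) || !nrow(per_tissue)) {
    gd_abort("gene_record requires a nonempty per_tissue profile table",
             "gd_contract_error")
  }
  if (anyDuplicated(per_tissue$tissue)) {
    gd_abort("per_tissue must cover each tissue exactly once",
             "gd_contract_error")
  }
  if (!focal_tissue %in% per_tissue$tissue) {
    gd_abort(sprintf("focal tissue %s absent from per_tissue", focal_tissue),
             "gd_contract_error")
  }
  need <- c("sample_id", "sex", "age_bracket", "tpm")
  if (!all(need %in% names(samples))) {
    gd_abort("samples must have sample_id, sex, age_bracket, tpm columns",
             "gd_contract_error")
  }
  structure(
    list(annotation = as.data.frame(annotation)[1, , drop = FALSE],
         per_tissue = as.data.frame(per_tissue),
         focal_tissue = focal_tissue,
         samples = as.data.frame(samples)),
    class = "gene_record"
  )
}

#' Build a gene record from a cohort and its scored profiles
#'
#' Convenience constructor for the single-tissue case: the focal samples are
#' taken from the cohort (masked values excluded) and the profile rows from
#' `profiles_list`.
#'
#' @param cohort the focal `tissue_cohort`.
#' @param profiles_list named list (or single `data.frame`) of scored
#'   per-tissue profile tables, all containing the gene.
#' @param gene_id versionless Ensembl gene identifier.
#' @return A [gene_record()].
#' @export
gene_record_from_cohort <- function(cohort, profiles_list, gene_id) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  if (is.data.frame(profiles_list)) {
    profiles_list <- list(profiles_list)
  }
  per_tissue <- do.call(rbind, lapply(profiles_list, function(p) {
    p[p$gene_id == gene_id, , drop = FALSE]
  }))
  gi <- match(gene_id, cohort$genes$gene_id)
  if (is.na(gi)) {
    gd_abort(sprintf("gene %s not in cohort %s", gene_id,
                     cohort$tissue_name), "gd_contract_error")
  }
  keep <- !cohort$mask[gi, ]
  samples <- data.frame(
    sample_id = cohort$samples$sample_id[keep],
    sex = cohort$samples$sex[keep],
    age_bracket = cohort$samples$age_bracket[keep],
    tpm = cohort$values[gi, keep],
    stringsAsFactors = FALSE
  )
  gene_record(cohort$genes[gi, , drop = FALSE], per_tissue,
              cohort$tissue_name, samples)
}

# Deterministic sample display order: males before females, ascending age
# bracket within sex, lexicographic sample id within bracket.
order_record_samples <- function(samples) {
  sex <- factor(samples$sex, levels = c("male", "female"))
  bracket <- factor(samples$age_bracket, levels = AGE_BRACKETS)
  samples[order(sex, bracket, samples$sample_id), , drop = FALSE]
}

scale_tpm <- function(tpm, axis_scale) {
  switch(axis_scale,
         tpm = tpm,
         log2 = log2(tpm + 1),
         log10 = log10(tpm + 1))
}

SEX_COLORS <- c(male = "#1f77b4", female = "#ff7f0e")  # blue / orange

#' Per-sample expression scatter for the focal tissue
#'
#' One point per sample: males (blue) plotted before females (orange), each
#' sex grouped by ascending age bracket (Age20 ... Age70+), sample id
#' lexicographic within a bracket. Log scales plot `log2(TPM + 1)` or
#' `log10(TPM + 1)` so undetectable expression stays at 0.
#'
#' @param record a [gene_record()] with at least one focal sample.
#' @param axis_scale `"tpm"`, `"log2"` or `"log10"`.
#' @param path optional output figure path (`.pdf`/`.svg`/`.png`); when
#'   `NULL` only the plot object is returned.
#' @return The ggplot object, invisibly; its data carries the plotted
#'   series in display order.
#' @export
gene_tissue_scatter <- function(record, axis_scale = c("tpm", "log2",
                                                       "log10"),
                                path = NULL) {
  stopifnot(inherits(record, "gene_record"))
  axis_scale <- match.arg(axis_scale)
  if (!nrow(record$samples)) {
    gd_abort("focal tissue has no samples to plot", "gd_contract_error")
  }
  df <- order_record_samples(record$samples)
  df$y <- scale_tpm(df$tpm, axis_scale)
  df$x <- factor(df$sample_id, levels = df$sample_id)
  ylab <- switch(axis_scale, tpm = "TPM", log2 = "log2(TPM + 1)",
                 log10 = "log10(TPM + 1)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, color = sex)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_color_manual(values = SEX_COLORS) +
    ggplot2::labs(
      title = sprintf("%s expression in %s",
                      record$annotation$gene_symbol, record$focal_tissue),
      x = "samples (male then female, by age bracket)", y = ylab,
      color = "sex") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(path, p, width = 8, height = 4)
  }
  invisible(p)
}

#' Cross-tissue male/female bar chart
#'
#' Paired male/female bars per tissue for either the Gini index or the TPM
#' mean, tissues in the (fixed) order of the record's `per_tissue` table.
#' Undefined values are rendered as absent bars, not zeros.
#'
#' @param record a [gene_record()].
#' @param metric `"gini"` or `"tpm_mean"`.
#' @param path optional output figure path.
#' @return The ggplot object, invisibly.
#' @export
cross_tissue_bars <- function(record, metric = c("gini", "tpm_mean"),
                              path = NULL) {
  stopifnot(inherits(record, "gene_record"))
  metric <- match.arg(metric)
  pt <- record$per_tissue
  cols <- if (metric == "gini") c("gini_M", "gini_F") else
    c("tpm_mean_M", "tpm_mean_F")
  long <- rbind(
    data.frame(tissue = pt$tissue, sex = "male", value = pt[[cols[1]]],
               stringsAsFactors = FALSE),
    data.frame(tissue = pt$tissue, sex = "female", value = pt[[cols[2]]],
               stringsAsFactors = FALSE)
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  long$tissue <- factor(long$tissue, levels = pt$tissue)
  long$sex <- factor(long$sex, levels = c("male", "female"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = tissue, y = value, fill = sex)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(preserve = "single"),
                      width = 0.7) +
    ggplot2::scale_fill_manual(values = SEX_COLORS) +
    ggplot2::labs(
      title = sprintf("%s: %s by tissue", record$annotation$gene_symbol,
                      if (metric == "gini") "Gini index" else "TPM mean"),
      x = NULL, y = if (metric == "gini") "Gini index" else "TPM mean",
      fill = "sex") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(path, p, width = 10, height = 4)
  }
  invisible(p)
}

# Round numeric fields to 6 significant digits, mapping NA/NaN to NULL-able
# NA so JSON serializes them as null.
signif_frame <- function(df, digits = 6L) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      v <- signif(df[[nm]], digits)
      v[!is.finite(v) & !is.na(df[[nm]])] <- NA_real_
      v[is.nan(v)] <- NA_real_
      df[[nm]] <- v
    }
  }
  df
}

#' Export a gene record as JSON
#'
#' Stable key order, numbers at 6 significant digits, undefined statistics
#' as JSON `null`. [read_gene_record()] restores the record;
#' export-read-export is idempotent at that precision.
#'
#' @param record a [gene_record()].
#' @param path optional output path.
#' @return The JSON string (class `json`), invisibly when `path` is given.
#' @export
export_gene_record <- function(record, path = NULL) {
  stopifnot(inherits(record, "gene_record"))
  payload <- list(
    annotation = signif_frame(record$annotation),
    focal_tissue = record$focal_tissue,
    per_tissue = signif_frame(record$per_tissue),
    samples = signif_frame(record$samples)
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           na = "null", null = "null", digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a gene record exported by [export_gene_record()]
#'
#' @param x path to a JSON file, or a JSON string.
#' @return A [gene_record()].
#' @export
read_gene_record <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  gene_record(obj$annotation, obj$per_tissue, obj$focal_tissue, obj$samples)
}
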