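# Tissue inclusion rules and per-tissue cohort assembly.

# The 11 GTEx V10 datasets excluded from analysis: two cultured cell lines,
# kidney_medulla (11 samples), and eight single-sex reproductive tissues.
# "cells_clultured_fibroblasts" is a spelling variant seen in the wild.
TISSUE_EXCLUSIONS <- c(
  "cells_cultured_fibroblasts",
  "cells_clultured_fibroblasts",
  "cells_ebv-transformed_lymphocytes",
  "kidney_medulla",
  "cervix_ectocervix",
  "cervix_endocervix",
  "fallopian_tube",
  "ovary",
  "prostate",
  "testis",
  "uterus",
  "vagina"
)

# Case-insensitive, hyphen/underscore/space tolerant canonical form so
# file-name dialects cannot silently bypass the exclusion list.
normalize_tissue_name <- function(x) {
  gsub("[-_ ]+", "_", tolower(trimws(as.character(x))))
}

#' Apply the tissue inclusion rules
#'
#' Removes the two cultured cell-line datasets, `kidney_medulla`, and the
#' eight single-sex reproductive tissues (cervix ectocervix/endocervix,
#' fallopian tube, ovary, prostate, testis, uterus, vagina) from a list of
#' per-tissue dataset names. Matching is case-insensitive and tolerant of
#' hyphen/underscore variants; unknown names pass through; order is
#' preserved. Applied to the 54 GTEx V10 dataset names this retains the 43
#' tissue subtypes used for Gini analysis.
#'
#' @param dataset_names character vector of per-tissue dataset names.
#' @return The retained names, in input order.
#' @export
select_tissues <- function(dataset_names) {
  if (!length(dataset_names)) {
    return(character(0))
  }
  excluded <- normalize_tissue_name(TISSUE_EXCLUSIONS)
  dataset_names[!(normalize_tissue_name(dataset_names) %in% excluded)]
}

#' Per-tissue sample counts for the analyzed GTEx V10 tissue subtypes
#'
#' Published male/female donor sample counts for the 43 GTEx V10 tissue
#' subtypes retained by [select_tissues()] (17,338 samples: 11,807 male,
#' 5,531 female). Shipped with the package so catalog arithmetic can be
#' exercised without downloading GTEx.
#'
#' @return `data.frame` with columns `tissue`, `n_male`, `n_female`.
#' @export
gtex_v10_sample_counts <- function() {
  path <- system.file("extdata", "gtex_v10_sample_counts.tsv",
                      package = "ginidimorph", mustWork = TRUE)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' The 54 GTEx V10 per-tissue dataset names
#'
#' The 43 analyzed tissue subtypes plus the 11 excluded datasets (cell
#' lines, kidney_medulla, single-sex tissues), in GTEx file naming.
#'
#' @return Character vector of length 54.
#' @export
gtex_v10_dataset_names <- function() {
  excluded <- setdiff(TISSUE_EXCLUSIONS, "cells_clultured_fibroblasts")
  sort(c(gtex_v10_sample_counts()$tissue, excluded))
}

#' Assemble a per-tissue, sex- and age-labelled cohort
#'
#' Restricts an expression matrix to (a) samples whose donor has resolved
#' sex and age-bracket phenotypes and (b) genes in the protein-coding
#' annotation universe (GENCODE protein_coding intersected with the genes
#' present in the expression file; chrM genes are excluded entirely since
#' they fit neither the autosome nor the XY query class). Row order follows
#' the annotation set. Samples whose donor lacks phenotype data are dropped
#' with a warning, not an error.
#'
#' @param matrix an [expression_matrix()].
#' @param phenotypes donor phenotype table from [read_subject_phenotypes()].
#' @param annotations protein-coding gene annotations from
#'   [read_gencode_protein_coding()].
#' @return An object of class `tissue_cohort`: the restricted values matrix,
#'   aligned sample annotations, gene annotations, a (initially empty)
#'   outlier mask, and `n_male`/`n_female` counts.
#' @export
build_cohort <- function(matrix, phenotypes, annotations) {
  stopifnot(inherits(matrix, "expression_matrix"))
  donor <- map_sample_to_donor(matrix$sample_ids)
  idx <- match(donor, phenotypes$donor_id)
  sex <- phenotypes$sex[idx]
  age <- phenotypes$age_bracket[idx]
  keep_sample <- !is.na(sex) & !is.na(age)
  n_dropped <- sum(!keep_sample)
  if (n_dropped > 0L) {
    warning(sprintf(
      "%s: dropped %d of %d samples lacking resolved sex/age phenotypes",
      matrix$tissue_name, n_dropped, length(keep_sample)), call. = FALSE)
  }

  genes <- annotations[annotations$chromosome != "chrM", , drop = FALSE]
  matrix_keys <- strip_gene_version(matrix$gene_ids)
  row_idx <- match(genes$gene_id, matrix_keys)
  genes <- genes[!is.na(row_idx), , drop = FALSE]
  row_idx <- row_idx[!is.na(row_idx)]

  samples <- data.frame(
    sample_id = matrix$sample_ids[keep_sample],
    donor_id = donor[keep_sample],
    sex = sex[keep_sample],
    age_bracket = age[keep_sample],
    stringsAsFactors = FALSE
  )
  n_male <- sum(samples$sex == "male")
  n_female <- sum(samples$sex == "female")
  if (n_male == 0L || n_female == 0L) {
    gd_abort(sprintf(
      "cohort %s has no %s samples after phenotype filtering; both sexes are required",
      matrix$tissue_name, if (n_male == 0L) "male" else "female"),
      "gd_cohort_error")
  }

  values <- matrix$values[row_idx, keep_sample, drop = FALSE]
  rownames(values) <- genes$gene_id
  genes$gene_symbol_expr <- matrix$gene_symbols[row_idx]
  rownames(genes) <- NULL

  structure(
    list(
      tissue_name = matrix$tissue_name,
      genes = genes,
      samples = samples,
      values = values,
      mask = matrix(FALSE, nrow = nrow(values), ncol = ncol(values),
                    dimnames = dimnames(values)),
      n_male = n_male,
      n_female = n_female
    ),
    class = "tissue_cohort"
  )
}

#' @export
print.tissue_cohort <- function(x, ...) {
  cat(sprintf(
    "<tissue_cohort> %s: %d protein-coding genes, %d samples (%dM/%dF), %d masked values\n",
    x$tissue_name, nrow(x$values), ncol(x$values), x$n_male, x$n_female,
    sum(x$mask)))
  invisible(x)
}

#' Summarize tissue cohorts into a sample-count catalog
#'
#' One row per tissue with male and female sample counts and the
#' male-to-female ratio rounded half-up to one decimal (the convention used
#' for reported ratios such as pancreas 1.6 and kidney_cortex 3.3). Grand
#' totals across tissues are attached as attributes `n_male_total` and
#' `n_female_total`.
#'
#' @param x either a list of `tissue_cohort` objects or a `data.frame` with
#'   columns `tissue`, `n_male`, `n_female` (every tissue must have at least
#'   one female sample).
#' @return `data.frame` with columns `tissue`, `n_male`, `n_female`,
#'   `ratio`.
#' @export
catalog_summary <- function(x) {
  if (is.data.frame(x)) {
    counts <- x[, c("tissue", "n_male", "n_female")]
  } else {
    stopifnot(all(vapply(x, inherits, logical(1), "tissue_cohort")))
    counts <- data.frame(
      tissue = vapply(x, `[[`, character(1), "tissue_name"),
      n_male = vapply(x, `[[`, integer(1), "n_male"),
      n_female = vapply(x, `[[`, integer(1), "n_female"),
      stringsAsFactors = FALSE
    )
  }
  if (any(counts$n_female < 1L)) {
    gd_abort("catalog requires every tissue to have >= 1 female sample",
             "gd_contract_error")
  }
  counts$ratio <- round_half_up(counts$n_male / counts$n_female, 1L)
  attr(counts, "n_male_total") <- sum(counts$n_male)
  attr(counts, "n_female_total") <- sum(counts$n_female)
  counts
}
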