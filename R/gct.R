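# GCT 1.2 expression matrix I/O.
#
# The per-tissue GTEx TPM files are GCT version 1.2: a "#1.2" version line, a
# "<n_genes>\t<n_samples>" dimensions line, then a header row with two
# annotation columns (gene id, gene description/symbol) followed by one
# column per sample.

#' Construct an expression matrix
#'
#' In-memory container for one tissue's genes x samples TPM matrix.
#'
#' @param tissue_name tissue subtype label (GTEx file naming, e.g.
#'   `"adipose_subcutaneous"`).
#' @param gene_ids character vector of Ensembl gene identifiers, version
#'   suffix retained as read; must be unique after version stripping.
#' @param gene_symbols parallel character vector of display names.
#' @param sample_ids character vector of unique sample identifiers.
#' @param values numeric matrix, rows = genes, columns = samples, all entries
#'   finite and `>= 0`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tissue_name, gene_ids, gene_symbols,
                              sample_ids, values) {
  values <- as.matrix(values)
  if (!is.numeric(values) && length(values)) {
    gd_abort("expression values must be numeric", "gd_format_error")
  }
  storage.mode(values) <- "double"
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    gd_abort(
      sprintf("values shape (%d x %d) does not match %d genes x %d samples",
              nrow(values), ncol(values), length(gene_ids),
              length(sample_ids)),
      "gd_dimension_error")
  }
  if (length(gene_symbols) != length(gene_ids)) {
    gd_abort("gene_symbols must parallel gene_ids", "gd_dimension_error")
  }
  if (length(values) && (anyNA(values) || any(!is.finite(values)))) {
    gd_abort("expression values contain missing or non-finite cells",
             "gd_format_error")
  }
  if (length(values) && any(values < 0)) {
    gd_abort("expression values contain negative cells", "gd_format_error")
  }
  if (anyDuplicated(strip_gene_version(gene_ids))) {
    gd_abort("gene identifiers are not unique after version stripping",
             "gd_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    gd_abort("sample identifiers are not unique", "gd_format_error")
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(
    list(
      tissue_name = tissue_name,
      gene_ids = as.character(gene_ids),
      gene_symbols = as.character(gene_symbols),
      sample_ids = as.character(sample_ids),
      values = values
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d genes x %d samples\n",
              x$tissue_name, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Infer a tissue label from a GTEx-style file name
# ("gene_tpm_v10_liver.gct" -> "liver").
tissue_from_filename <- function(path) {
  name <- tools::file_path_sans_ext(basename(path))
  sub("^gene_tpm(_v[0-9]+)?_", "", name)
}

#' Read a GCT 1.2 expression file
#'
#' Parses and validates a GCT 1.2 matrix as distributed per tissue by the
#' GTEx portal. Parsing is locale-independent ("." decimal separator);
#' negative, missing or non-numeric data cells are rejected rather than
#' coerced.
#'
#' @param path path to a `.gct` file.
#' @param tissue_name optional tissue label; defaults to the file name with
#'   any `gene_tpm[_vNN]_` prefix removed.
#' @return An [expression_matrix()].
#' @export
read_gct <- function(path, tissue_name = NULL) {
  if (!file.exists(path)) {
    gd_abort(sprintf("GCT file not found: %s", path), "gd_io_error")
  }
  header <- readLines(path, n = 3L)
  if (length(header) < 3L) {
    gd_abort(sprintf("malformed GCT header in %s: fewer than 3 header lines",
                     path), "gd_format_error")
  }
  if (trimws(header[1L]) != "#1.2") {
    gd_abort(sprintf("malformed GCT version line in %s: '%s' (expected #1.2)",
                     path, header[1L]), "gd_format_error")
  }
  dims <- strsplit(trimws(header[2L]), "\t", fixed = TRUE)[[1L]]
  if (length(dims) != 2L || anyNA(suppressWarnings(as.integer(dims)))) {
    gd_abort(sprintf("malformed GCT dimensions line in %s: '%s'",
                     path, header[2L]), "gd_format_error")
  }
  n_genes <- as.integer(dims[1L])
  n_samples <- as.integer(dims[2L])

  # take sample ids from the raw header row: fread would silently rename
  # duplicated column names instead of failing
  header_cols <- strsplit(header[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header_cols) < 2L) {
    gd_abort(sprintf("malformed GCT column header in %s: '%s'",
                     path, header[3L]), "gd_format_error")
  }
  declared_samples <- header_cols[-(1:2)]
  if (anyDuplicated(declared_samples)) {
    gd_abort(sprintf("duplicate sample identifier(s) in %s: %s", path,
                     paste(unique(declared_samples[
                       duplicated(declared_samples)]), collapse = ", ")),
             "gd_format_error")
  }

  tab <- data.table::fread(path, skip = 2L, header = TRUE, sep = "\t",
                           check.names = FALSE, data.table = FALSE,
                           colClasses = list(character = 1:2), dec = ".")
  if (ncol(tab) != n_samples + 2L) {
    gd_abort(sprintf(
      "GCT dimension mismatch in %s: declared %d samples, observed %d",
      path, n_samples, ncol(tab) - 2L), "gd_dimension_error")
  }
  if (nrow(tab) != n_genes) {
    gd_abort(sprintf(
      "GCT dimension mismatch in %s: declared %d genes, observed %d rows",
      path, n_genes, nrow(tab)), "gd_dimension_error")
  }
  sample_cols <- tab[, -(1:2), drop = FALSE]
  if (nrow(sample_cols)) {
    numeric_ok <- vapply(sample_cols, is.numeric, logical(1))
    if (!all(numeric_ok)) {
      gd_abort(sprintf(
        "non-numeric expression cells in %s (columns: %s)",
        path, paste(names(sample_cols)[!numeric_ok], collapse = ", ")),
        "gd_format_error")
    }
  }
  values <- as.matrix(sample_cols)
  if (!nrow(values)) {
    values <- matrix(numeric(0), nrow = 0L, ncol = n_samples)
  }
  expression_matrix(
    tissue_name = tissue_name %||% tissue_from_filename(path),
    gene_ids = tab[[1L]],
    gene_symbols = tab[[2L]],
    sample_ids = declared_samples,
    values = values
  )
}

#' Write a GCT 1.2 expression file
#'
#' Inverse of [read_gct()]: writing then re-reading reproduces the matrix
#' exactly (values are serialized at full double precision).
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c("#1.2",
               paste(length(x$gene_ids), length(x$sample_ids), sep = "\t")),
             path)
  tab <- data.frame(Name = x$gene_ids, Description = x$gene_symbols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (length(x$sample_ids)) {
    tab <- cbind(tab, as.data.frame(x$values, optional = TRUE))
    names(tab) <- c("Name", "Description", x$sample_ids)
  }
  data.table::fwrite(tab, path, sep = "\t", append = TRUE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
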