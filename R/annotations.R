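# Gene annotation inputs: GENCODE GTF (protein-coding universe) and the MANE
# Select summary (cross-reference annotation; never a filter).

normalize_chromosome <- function(x) {
  x <- as.character(x)
  x[x == "MT"] <- "M"
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Read protein-coding gene annotations from a GENCODE GTF
#'
#' Keeps gene-level records whose `gene_type` attribute is
#' `"protein_coding"`. The Ensembl version suffix is stripped for the join
#' key (`gene_id`) but retained verbatim for display
#' (`gene_id_version`); chromosome names are normalized to the
#' `chr`-prefixed convention.
#'
#' @param path path to a GTF file (GENCODE attribute dialect).
#' @return `data.frame` with columns `gene_id` (versionless),
#'   `gene_id_version`, `gene_symbol`, `chromosome`, `gene_type`.
#' @export
read_gencode_protein_coding <- function(path) {
  if (!file.exists(path)) {
    gd_abort(sprintf("GTF file not found: %s", path), "gd_io_error")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      gd_abort(sprintf("failed to parse GTF %s: %s", path,
                       conditionMessage(e)), "gd_format_error")
    })
  meta <- as.data.frame(gr)
  if (!nrow(meta) || !all(c("type", "gene_id") %in% names(meta))) {
    return(data.frame(gene_id = character(), gene_id_version = character(),
                      gene_symbol = character(), chromosome = character(),
                      gene_type = character(), stringsAsFactors = FALSE))
  }
  if (!"gene_type" %in% names(meta)) {
    # Ensembl-dialect files call the same attribute gene_biotype.
    if ("gene_biotype" %in% names(meta)) {
      meta$gene_type <- meta$gene_biotype
    } else {
      gd_abort(sprintf("GTF %s lacks a gene_type attribute", path),
               "gd_format_error")
    }
  }
  keep <- meta$type == "gene" & meta$gene_type == "protein_coding"
  meta <- meta[keep, , drop = FALSE]
  symbol <- if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id
  out <- data.frame(
    gene_id = strip_gene_version(meta$gene_id),
    gene_id_version = meta$gene_id,
    gene_symbol = as.character(symbol),
    chromosome = normalize_chromosome(meta$seqnames),
    gene_type = meta$gene_type,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read the MANE Select summary table
#'
#' Keeps rows whose `MANE_status` is `"MANE Select"` from a MANE summary TSV
#' (as in `MANE.GRCh38.v1.4.summary.txt`). Keys are versionless Ensembl gene
#' identifiers; a duplicated MANE Select record for one gene is an error.
#' MANE is annotation-only in this package: it decorates gene records and is
#' never used to filter the analysis universe.
#'
#' @param path path to the summary TSV; must contain a `MANE_status` column.
#' @return `data.frame` keyed by `ensembl_gene_id` with cross-reference
#'   columns `gene_symbol`, `gene_name`, `ncbi_gene_id`, `refseq_nm`,
#'   `refseq_np`, `ensembl_transcript_id`, `ensembl_protein_id`,
#'   `mane_status`.
#' @export
read_mane_select <- function(path) {
  if (!file.exists(path)) {
    gd_abort(sprintf("MANE summary file not found: %s", path), "gd_io_error")
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  if (!"MANE_status" %in% names(tab)) {
    gd_abort(sprintf("MANE summary %s lacks the MANE_status column", path),
             "gd_format_error")
  }
  tab <- tab[tab$MANE_status == "MANE Select", , drop = FALSE]
  col <- function(nm) {
    if (nm %in% names(tab)) as.character(tab[[nm]]) else
      rep(NA_character_, nrow(tab))
  }
  out <- data.frame(
    ensembl_gene_id = strip_gene_version(col("Ensembl_Gene")),
    gene_symbol = col("symbol"),
    gene_name = col("name"),
    ncbi_gene_id = col("NCBI_GeneID"),
    refseq_nm = col("RefSeq_nuc"),
    refseq_np = col("RefSeq_prot"),
    ensembl_transcript_id = col("Ensembl_nuc"),
    ensembl_protein_id = col("Ensembl_prot"),
    mane_status = col("MANE_status"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$ensembl_gene_id)
  if (any(dup)) {
    gd_abort(sprintf("duplicate MANE Select record(s) for gene(s): %s",
                     paste(unique(out$ensembl_gene_id[dup]), collapse = ", ")),
             "gd_format_error")
  }
  rownames(out) <- NULL
  out
}
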