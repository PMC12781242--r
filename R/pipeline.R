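# End-to-end pipeline entry points. A thin command-line wrapper over these
# functions ships at inst/cli/ginidimorph.

#' Run the full profiling pipeline over a directory of GCT files
#'
#' For every retained tissue (after [select_tissues()]): read the GCT
#' matrix, assemble the phenotype-labelled protein-coding cohort, detect and
#' mask singleton extreme outliers, recompute sex-stratified profiles, fill
#' divergence Z-scores, and write `<tissue>.profiles.tsv`. Also writes
#' `exclusions.tsv` (the outlier log), `catalog.tsv` (per-tissue sample
#' counts and M/F ratios) and `annotations.tsv` (GENCODE joined with MANE
#' Select cross-references). Outputs are deterministic: rerunning on
#' unchanged inputs is byte-identical.
#'
#' @param input_dir directory of per-tissue `.gct` files.
#' @param phenotype_path subject phenotypes TSV.
#' @param gtf_path GENCODE-dialect GTF.
#' @param mane_path MANE summary TSV.
#' @param output_dir output directory (created if needed).
#' @param outlier_z singleton Z gate (default 15).
#' @param outlier_gini mean-Gini gate (default 0.97).
#' @param quiet suppress per-tissue progress messages.
#' @return Invisibly, a list with `profiles` (named list of scored profile
#'   tables), `catalog`, `exclusions`, and `paths`.
#' @export
pipeline_profile <- function(input_dir, phenotype_path, gtf_path, mane_path,
                             output_dir, outlier_z = 15,
                             outlier_gini = 0.97, quiet = FALSE) {
  for (p in c(phenotype_path, gtf_path, mane_path)) {
    if (!file.exists(p)) {
      gd_abort(sprintf("input stage: required file not found: %s", p),
               "gd_io_error")
    }
  }
  gct_files <- sort(list.files(input_dir, pattern = "\\.gct$",
                               full.names = TRUE))
  if (!length(gct_files)) {
    gd_abort(sprintf("input stage: no .gct files in %s", input_dir),
             "gd_io_error")
  }
  tissues <- unname(vapply(gct_files, tissue_from_filename, character(1)))
  retained <- select_tissues(tissues)
  gct_files <- gct_files[tissues %in% retained]
  tissues <- tissues[tissues %in% retained]

  phenotypes <- read_subject_phenotypes(phenotype_path)
  annotations <- read_gencode_protein_coding(gtf_path)
  mane <- read_mane_select(mane_path)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  profiles <- list()
  cohorts <- list()
  exclusions <- list()
  for (k in seq_along(gct_files)) {
    tissue <- tissues[k]
    em <- read_gct(gct_files[k], tissue_name = tissue)
    cohort <- build_cohort(em, phenotypes, annotations)
    if (!quiet) {
      message(sprintf("%s: %d genes, %d male / %d female samples", tissue,
                      nrow(cohort$values), cohort$n_male, cohort$n_female))
    }
    records <- find_extreme_singletons(cohort, z_threshold = outlier_z,
                                       gini_threshold = outlier_gini)
    cohort <- apply_exclusions(cohort, records)
    prof <- divergence_zscores(compute_profiles(cohort))
    write_profile_table(prof, file.path(output_dir,
                                        paste0(tissue, ".profiles.tsv")))
    profiles[[tissue]] <- prof
    cohorts[[tissue]] <- cohort
    exclusions[[tissue]] <- records
  }

  exclusions <- do.call(rbind, exclusions)
  rownames(exclusions) <- NULL
  write_exclusion_log(exclusions, file.path(output_dir, "exclusions.tsv"))

  catalog <- catalog_summary(cohorts)
  data.table::fwrite(catalog, file.path(output_dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE)

  ann <- merge(annotations, mane, by.x = "gene_id",
               by.y = "ensembl_gene_id", all.x = TRUE,
               suffixes = c("", "_mane"), sort = TRUE)
  data.table::fwrite(ann, file.path(output_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")

  invisible(list(profiles = profiles, catalog = catalog,
                 exclusions = exclusions,
                 paths = list(output_dir = output_dir)))
}

#' Query one tissue's scored profile table for divergent genes
#'
#' @param profile_path a `<tissue>.profiles.tsv` written by
#'   [pipeline_profile()].
#' @param z_cutoff,tpm_cutoff,chrom_class,direction query parameters; see
#'   [divergence_query()].
#' @param out_path optional TSV path for the selected genes.
#' @return The [query_divergent()] result, invisibly when `out_path` is
#'   given.
#' @export
pipeline_query <- function(profile_path, z_cutoff = 2.58, tpm_cutoff = 1.0,
                           chrom_class = "autosome",
                           direction = "M_greater", out_path = NULL) {
  profiles <- read_profile_table(profile_path)
  res <- query_divergent(profiles, divergence_query(z_cutoff, tpm_cutoff,
                                                    chrom_class, direction))
  if (!is.null(out_path)) {
    write_profile_table(res$genes, out_path)
    return(invisible(res))
  }
  res
}

#' Simulate a cohort and write pipeline-ready fixture files
#'
#' Runs [simulate_cohort()] (plus [inject_spike_outliers()] when
#' `spike_count > 0`), writes the GCT/phenotype/GTF/MANE fixture set via
#' [write_fixture_files()], the ground-truth gene classes to `truth.tsv`,
#' and any injected spikes to `injected_spikes.tsv`.
#'
#' @param output_dir output directory.
#' @param config a [sim_config()].
#' @param tissue_name simulated tissue label.
#' @return Invisibly, a list with `cohort`, `truth`, `injected`, `paths`.
#' @export
pipeline_simulate <- function(output_dir, config = sim_config(),
                              tissue_name = "sim_tissue") {
  sim <- simulate_cohort(config, tissue_name)
  injected <- NULL
  if (config$spike_count > 0L) {
    spiked <- inject_spike_outliers(sim$cohort, config)
    sim$cohort <- spiked$cohort
    injected <- spiked$injected
  }
  paths <- write_fixture_files(sim$cohort, output_dir)
  truth_path <- file.path(output_dir, "truth.tsv")
  data.table::fwrite(sim$truth, truth_path, sep = "\t", quote = FALSE)
  paths$truth <- truth_path
  if (!is.null(injected)) {
    spike_path <- file.path(output_dir, "injected_spikes.tsv")
    data.table::fwrite(injected, spike_path, sep = "\t", quote = FALSE)
    paths$injected <- spike_path
  }
  invisible(list(cohort = sim$cohort, truth = sim$truth,
                 injected = injected, paths = paths))
}
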