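# Readers and writers for the standard input formats.

test_that("read_gct parses a valid file and the empty case", {
  path <- tempfile(fileext = ".gct")
  write_text(c("#1.2", "2\t3",
               "Name\tDescription\tS-1-A\tS-2-A\tS-3-A",
               "ENSG00000000001.5\tAAA\t1.5\t0\t2",
               "ENSG00000000002.1\tBBB\t0\t0\t10"), path)
  em <- read_gct(path, tissue_name = "toy")
  expect_s3_class(em, "expression_matrix")
  expect_equal(dim(em), c(2L, 3L))
  expect_equal(em$gene_ids, c("ENSG00000000001.5", "ENSG00000000002.1"))
  expect_equal(unname(em$values[1, ]), c(1.5, 0, 2))

  empty <- tempfile(fileext = ".gct")
  write_text(c("#1.2", "0\t3", "Name\tDescription\tS1\tS2\tS3"), empty)
  em0 <- read_gct(empty, tissue_name = "toy")
  expect_equal(dim(em0), c(0L, 3L))
  expect_equal(em0$sample_ids, c("S1", "S2", "S3"))
})

test_that("read_gct rejects malformed headers, dimensions and cells", {
  bad_version <- write_text(c("#1.3", "1\t1", "Name\tDescription\tS1",
                              "G1\tg\t1"), tempfile())
  expect_error(read_gct(bad_version), class = "gd_format_error")

  bad_dims <- write_text(c("#1.2", "5\t3", "Name\tDescription\tS1\tS2\tS3",
                           "G1\tg\t1\t2\t3", "G2\tg\t1\t2\t3",
                           "G3\tg\t1\t2\t3", "G4\tg\t1\t2\t3"), tempfile())
  expect_error(read_gct(bad_dims), class = "gd_dimension_error")
  expect_error(read_gct(bad_dims), "declared 5")

  bad_cols <- write_text(c("#1.2", "1\t3", "Name\tDescription\tS1\tS2",
                           "G1\tg\t1\t2"), tempfile())
  expect_error(read_gct(bad_cols), class = "gd_dimension_error")

  negative <- write_text(c("#1.2", "1\t2", "Name\tDescription\tS1\tS2",
                           "G1\tg\t-1\t2"), tempfile())
  expect_error(read_gct(negative), class = "gd_format_error")

  textual <- write_text(c("#1.2", "1\t2", "Name\tDescription\tS1\tS2",
                          "G1\tg\tlow\t2"), tempfile())
  expect_error(read_gct(textual), class = "gd_format_error")

  dup_samples <- write_text(c("#1.2", "1\t2", "Name\tDescription\tS1\tS1",
                              "G1\tg\t1\t2"), tempfile())
  expect_error(read_gct(dup_samples), class = "gd_format_error")
})

test_that("write_gct round-trips through read_gct", {
  withr::with_seed(5, {
    em <- expression_matrix(
      "toy", sprintf("ENSG%08d.2", 1:3), c("A", "B", "C"),
      sprintf("GTEX-%04d-SM", 1:4),
      matrix(round(rlnorm(12, 1, 2), 6), nrow = 3))
  })
  path <- tempfile(fileext = ".gct")
  write_gct(em, path)
  back <- read_gct(path, tissue_name = "toy")
  expect_equal(back$gene_ids, em$gene_ids)
  expect_equal(back$gene_symbols, em$gene_symbols)
  expect_equal(back$sample_ids, em$sample_ids)
  expect_equal(back$values, em$values, tolerance = 1e-7)
})

test_that("subject phenotypes decode GTEx sex and age conventions", {
  path <- write_text(c("SUBJID\tSEX\tAGE",
                       "GTEX-AAAA\t1\t60-69",
                       "GTEX-BBBB\t2\t70-79",
                       "GTEX-CCCC\tFemale\t20-29",
                       "GTEX-DDDD\t3\t45",
                       "GTEX-EEEE\tmale\t30-39"), tempfile())
  ph <- read_subject_phenotypes(path)
  expect_equal(ph$donor_id[1], "GTEX-AAAA")
  expect_equal(ph$sex, c("male", "female", "female", NA, "male"))
  expect_equal(ph$age_bracket, c("60", "70+", "20", NA, "30"))

  empty <- write_text("SUBJID\tSEX\tAGE", tempfile())
  expect_equal(nrow(read_subject_phenotypes(empty)), 0L)

  missing_col <- write_text(c("SUBJID\tSEX", "GTEX-AAAA\t1"), tempfile())
  expect_error(read_subject_phenotypes(missing_col),
               class = "gd_format_error")
})

test_that("sample-to-donor mapping takes the first two hyphen tokens", {
  expect_equal(map_sample_to_donor("GTEX-X4EP-0011-R10a-SM-XXXXX"),
               "GTEX-X4EP")
  expect_equal(map_sample_to_donor(c("GTEX-AAAA-0001", "GTEX-BB-2")),
               c("GTEX-AAAA", "GTEX-BB"))
  expect_error(map_sample_to_donor("GTEXAAAA"),
               class = "gd_identifier_error")
})

gtf_line <- function(chrom, feature, id, type, name) {
  sprintf('%s\tHAVANA\t%s\t1\t1000\t.\t+\t.\tgene_id "%s"; gene_type "%s"; gene_name "%s";',
          chrom, feature, id, type, name)
}

test_that("GENCODE reader keeps protein-coding gene records only", {
  path <- write_text(c(
    gtf_line("chr1", "gene", "ENSG00000123456.7", "protein_coding", "AAA"),
    gtf_line("chr1", "transcript", "ENSG00000123456.7", "protein_coding", "AAA"),
    gtf_line("chrX", "gene", "ENSG00000000002.3", "protein_coding", "BBB"),
    gtf_line("chr2", "gene", "ENSG00000000003.1", "lncRNA", "CCC")
  ), tempfile(fileext = ".gtf"))
  ann <- read_gencode_protein_coding(path)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$gene_id, c("ENSG00000123456", "ENSG00000000002"))
  expect_equal(ann$gene_id_version[1], "ENSG00000123456.7")
  expect_equal(ann$chromosome, c("chr1", "chrX"))

  transcripts_only <- write_text(
    gtf_line("chr1", "transcript", "ENSG00000000009.1", "protein_coding", "T"),
    tempfile(fileext = ".gtf"))
  expect_equal(nrow(read_gencode_protein_coding(transcripts_only)), 0L)
})

mane_header <- paste("#NCBI_GeneID", "Ensembl_Gene", "HGNC_ID", "symbol",
                     "name", "RefSeq_nuc", "RefSeq_prot", "Ensembl_nuc",
                     "Ensembl_prot", "MANE_status", "GRCh38_chr",
                     "chr_start", "chr_end", "chr_strand", sep = "\t")
mane_row <- function(gene, status, symbol = "SYM") {
  paste("GeneID:1", gene, "HGNC:1", symbol, "a gene", "NM_1.1", "NP_1.1",
        "ENST1.1", "ENSP1.1", status, "chr1", "1", "2", "+", sep = "\t")
}

test_that("MANE reader keeps MANE Select rows keyed by versionless gene id", {
  path <- write_text(c(mane_header,
                       mane_row("ENSG00000000001.4", "MANE Select"),
                       mane_row("ENSG00000000002.2", "MANE Plus Clinical")),
                     tempfile())
  mane <- read_mane_select(path)
  expect_equal(nrow(mane), 1L)
  expect_equal(mane$ensembl_gene_id, "ENSG00000000001")
  expect_equal(mane$mane_status, "MANE Select")

  dup <- write_text(c(mane_header,
                      mane_row("ENSG00000000001.4", "MANE Select"),
                      mane_row("ENSG00000000001.5", "MANE Select")),
                    tempfile())
  expect_error(read_mane_select(dup), "ENSG00000000001")

  empty <- write_text(mane_header, tempfile())
  expect_equal(nrow(read_mane_select(empty)), 0L)

  no_status <- write_text("Ensembl_Gene\tsymbol", tempfile())
  expect_error(read_mane_select(no_status), class = "gd_format_error")
})

test_that("profile tables round-trip with NA for undefined statistics", {
  values <- rbind(c(4, 1, 2, 3), c(0, 0, 0, 0))
  cohort <- toy_cohort(values, c("male", "male", "female", "female"))
  profiles <- compute_profiles(cohort)
  path <- tempfile(fileext = ".tsv")
  write_profile_table(profiles, path)
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  expect_true(all(c("Gini_index_M", "Gini_index_F", "Gini_index_M-F",
                    "Gini_index_M-F_Zscore", "TPM_mean", "TPM_mean_M",
                    "TPM_mean_F", "TPM_mean_M/F") %in% header))
  expect_true(any(grepl("\tNA", readLines(path)[3])))  # all-zero gene
  back <- read_profile_table(path)
  expect_equal(back$gini_M, profiles$gini_M, tolerance = 1e-7)
  expect_equal(back$tpm_mean, profiles$tpm_mean, tolerance = 1e-7)
  expect_true(is.na(back$gini_M[2]))

  empty_path <- tempfile(fileext = ".tsv")
  write_profile_table(profiles[0, ], empty_path)
  expect_equal(length(readLines(empty_path)), 1L)

  mixed <- rbind(profiles, transform(profiles, tissue = "other"))
  expect_error(write_profile_table(mixed, tempfile()),
               class = "gd_contract_error")
})
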