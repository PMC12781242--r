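# Sex-stratified profiles, divergence Z-scores, query and counts.

test_that("profiles reproduce hand-computed Gini and TPM statistics", {
  # gene A: males (1,3) -> Gini 0.25; females (2,2) -> Gini 0
  values <- rbind(c(1, 3, 2, 2), c(0, 0, 0, 0))
  cohort <- toy_cohort(values, c("male", "male", "female", "female"))
  profiles <- compute_profiles(cohort)
  expect_equal(profiles$gini_M[1], 0.25)
  expect_equal(profiles$gini_F[1], 0)
  expect_equal(profiles$gini_diff[1], 0.25)
  expect_equal(profiles$tpm_mean_M[1], 2)
  expect_equal(profiles$tpm_mean_F[1], 2)
  expect_equal(profiles$tpm_ratio_MF[1], 1)
  expect_equal(profiles$tpm_mean[1], 2)

  # all-zero gene: Gini undefined in both sexes, means 0, ratio undefined
  expect_true(is.na(profiles$gini_M[2]))
  expect_true(is.na(profiles$gini_F[2]))
  expect_true(is.na(profiles$gini_diff[2]))
  expect_true(is.na(profiles$tpm_ratio_MF[2]))
  expect_equal(profiles$tpm_mean[2], 0)

  # overall mean is the count-weighted pooled mean
  values2 <- rbind(c(10, 10, 10, 1))
  cohort2 <- toy_cohort(values2, c("male", "male", "male", "female"))
  p2 <- compute_profiles(cohort2)
  expect_equal(p2$tpm_mean, (3 * 10 + 1) / 4)
  expect_true(p2$tpm_mean >= min(p2$tpm_mean_M, p2$tpm_mean_F))
  expect_true(p2$tpm_mean <= max(p2$tpm_mean_M, p2$tpm_mean_F))
})

make_scored <- function(diffs, tpm = NULL, chrom = NULL, symbols = NULL) {
  n <- length(diffs)
  profiles <- data.frame(
    gene_id = sprintf("ENSG%08d", seq_len(n)),
    gene_symbol = if (is.null(symbols)) sprintf("SYM%02d", seq_len(n)) else
      symbols,
    chromosome = if (is.null(chrom)) rep("chr1", n) else chrom,
    tissue = "toy_tissue",
    n_M = 10L, n_F = 10L,
    gini_M = NA_real_, gini_F = NA_real_,
    gini_diff = diffs,
    gini_diff_z = NA_real_,
    tpm_mean = if (is.null(tpm)) rep(5, n) else tpm,
    tpm_mean_M = 5, tpm_mean_F = 5, tpm_ratio_MF = 1,
    stringsAsFactors = FALSE
  )
  divergence_zscores(profiles)
}

test_that("divergence Z-scores follow the zscores contract per tissue", {
  scored <- make_scored(c(0, 0, 0, 0, 0.5))
  expect_equal(scored$gini_diff_z[5], 1.788854, tolerance = 1e-6)
  expect_equal(mean(scored$gini_diff_z), 0, tolerance = 1e-12)

  expect_equal(make_scored(rep(0.2, 4))$gini_diff_z, rep(0, 4))

  # undefined differences keep undefined Z and are excluded from the pool
  scored_na <- make_scored(c(0.1, NA, -0.1, 0.2))
  expect_true(is.na(scored_na$gini_diff_z[2]))
  expect_equal(mean(scored_na$gini_diff_z, na.rm = TRUE), 0,
               tolerance = 1e-12)
  expect_equal(sd(scored_na$gini_diff_z, na.rm = TRUE), 1,
               tolerance = 1e-9)

  expect_error(make_scored(c(0.5, NA, NA)), class = "gd_domain_error")
})

test_that("query filtering, ordering and direction semantics", {
  scored <- make_scored(
    c(0.6, -0.6, 0.01, 0.02, -0.01, 0, 0.01, -0.02, 0.4, -0.4),
    tpm = c(5, 5, 5, 5, 5, 5, 5, 5, 0.2, 5),
    chrom = c(rep("chr1", 8), "chr2", "chrX"))
  q_m <- query_divergent(scored, divergence_query(1.0, 1.0, "autosome",
                                                  "M_greater"))
  q_f <- query_divergent(scored, divergence_query(1.0, 1.0, "autosome",
                                                  "F_greater"))
  # gene 9 passes Z but fails the TPM cutoff; gene 10 passes Z but is chrX
  expect_equal(q_m$genes$gene_id, "ENSG00000001")
  expect_equal(q_f$genes$gene_id, "ENSG00000002")
  expect_length(intersect(q_m$genes$gene_id, q_f$genes$gene_id), 0L)

  q_xy <- query_divergent(scored, divergence_query(1.0, 1.0, "XY",
                                                   "F_greater"))
  expect_equal(q_xy$genes$gene_id, "ENSG00000010")

  # impossible cutoff
  expect_equal(query_divergent(scored, divergence_query(1e9))$count, 0L)

  # deterministic ordering: |Z| descending, symbol ascending on ties
  tied <- make_scored(c(0.5, 0.5, -0.1, -0.2, -0.2, -0.5),
                      symbols = c("ZZZ", "AAA", "M1", "M2", "M3", "M4"))
  res <- query_divergent(tied, divergence_query(0.1, 0, "autosome",
                                                "M_greater"))
  expect_equal(res$genes$gene_symbol[1:2], c("AAA", "ZZZ"))
  expect_equal(res$count, nrow(res$genes))
})

test_that("counts match a brute-force filter and are cutoff-monotone", {
  sims <- lapply(1:3, function(k) {
    sim <- simulate_cohort(sim_config(n_genes = 300, n_male = 60,
                                      n_female = 40, seed = 100 + k),
                           tissue_name = paste0("tissue_", k))
    divergence_zscores(compute_profiles(sim$cohort))
  })
  names(sims) <- vapply(sims, function(p) p$tissue[1], character(1))
  counts <- count_divergent(sims, z_cutoff = 1.5, tpm_cutoff = 1.0)

  brute <- vapply(sims, function(p) {
    auto <- p$chromosome %in% paste0("chr", 1:22)
    ok <- !is.na(p$gini_diff_z) & !is.na(p$tpm_mean)
    sum(ok & auto & p$gini_diff_z >= 1.5 & p$tpm_mean >= 1.0)
  }, integer(1))
  expect_equal(counts$n_M_greater, unname(brute))

  # monotonicity under stricter cutoffs
  stricter_z <- count_divergent(sims, z_cutoff = 2.58, tpm_cutoff = 1.0)
  stricter_tpm <- count_divergent(sims, z_cutoff = 1.5, tpm_cutoff = 10)
  expect_true(all(stricter_z$n_M_greater <= counts$n_M_greater))
  expect_true(all(stricter_z$n_F_greater <= counts$n_F_greater))
  expect_true(all(stricter_tpm$n_M_greater <= counts$n_M_greater))

  # autosome + XY partition the unrestricted-chromosome result
  p1 <- sims[[1]]
  for (dir in c("M_greater", "F_greater")) {
    n_auto <- query_divergent(p1, divergence_query(1.5, 1, "autosome",
                                                   dir))$count
    n_xy <- query_divergent(p1, divergence_query(1.5, 1, "XY", dir))$count
    z <- p1$gini_diff_z
    pass <- if (dir == "M_greater") !is.na(z) & z >= 1.5 else
      !is.na(z) & z <= -1.5
    n_all <- sum(pass & p1$tpm_mean >= 1)
    expect_equal(n_auto + n_xy, n_all)
  }

  expect_equal(nrow(count_divergent(list())), 0L)
})
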