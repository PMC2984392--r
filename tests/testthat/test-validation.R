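test_that("technical replicate correlation is 1 for identical arrays and matches the oracle", {
  cfg <- test_config(n_technical_replicates = 2, noise_cv = 0, seed = 12)
  coh <- simulate_cohort(cfg)
  d <- build_pools(coh, cfg)
  ras0 <- allelotype(simulate_intensities(d, coh, cfg), "pm_only")
  tech0 <- replicate_correlation(ras0, "technical")
  expect_identical(nrow(tech0), 2L)
  expect_equal(tech0$r, rep(1, 2), tolerance = 1e-12)

  cfgn <- test_config(n_technical_replicates = 2, noise_cv = 0.15, seed = 12)
  rasn <- allelotype(simulate_intensities(d, coh, cfgn), "pm_only")
  techn <- replicate_correlation(rasn, "technical")
  expect_true(all(techn$r < 1))
  for (i in seq_len(nrow(techn))) {
    a <- rasn[rasn$array_id == techn$array_1[i], ]
    b <- rasn[rasn$array_id == techn$array_2[i], ]
    expect_equal(techn$r[i],
                 oracle_pearson(a$ras, b$ras[match(a$snp_id, b$snp_id)]),
                 tolerance = 1e-12)
  }
})

test_that("biological replicate mean correlation matches a hand-coded mean of pairwise r", {
  cfg <- test_config(n_cases = 300, n_controls = 96, n_snps = 60,
                     target_pool_size = 24, noise_cv = 0.1, seed = 13,
                     n_technical_replicates = 0)
  coh <- simulate_cohort(cfg)
  d <- build_pools(coh, cfg)
  ras <- allelotype(simulate_intensities(d, coh, cfg), "pm_only")
  bio <- replicate_correlation(ras, "biological", d)
  expect_gt(nrow(bio), 0)
  m <- matrix(NA_real_, nrow = length(unique(ras$pool_id)),
              ncol = length(unique(ras$snp_id)),
              dimnames = list(sort(unique(ras$pool_id)), unique(ras$snp_id)))
  m[cbind(match(ras$pool_id, rownames(m)), match(ras$snp_id, colnames(m)))] <- ras$ras
  g <- bio$replicate_group[1]
  pools <- d$pool_table$pool_id[!is.na(d$pool_table$replicate_group) &
                                  d$pool_table$replicate_group == g]
  rs <- c()
  for (i in seq_len(length(pools) - 1)) for (j in (i + 1):length(pools))
    rs <- c(rs, oracle_pearson(m[pools[i], ], m[pools[j], ]))
  expect_equal(bio$mean_r[1], mean(rs), tolerance = 1e-12)
  expect_error(replicate_correlation(ras, "biological"), "pool design")
})

test_that("constant RAS vectors are skipped with a warning", {
  m <- matrix(0.5, nrow = 2, ncol = 5,
              dimnames = list(c("p1", "p1b"), paste0("s", 1:5)))
  ras <- manual_ras(m)
  ras$pool_id <- "p1"  # two arrays of one pool
  expect_warning(out <- replicate_correlation(ras, "technical"), "constant")
  expect_identical(nrow(out), 0L)
})

truth_fixture <- function(noise_cv = 0, seed = 14, n_snps = 40, ...) {
  cfg <- test_config(n_cases = 192, n_controls = 192, n_snps = n_snps,
                     noise_cv = noise_cv, background_level = 0,
                     cross_hyb_fraction = 0, control_blood_fraction = 0.5,
                     seed = seed, ...)
  coh <- simulate_cohort(cfg)
  d <- build_pools(coh, cfg)
  ras <- allelotype(simulate_intensities(d, coh, cfg), "pm_only")
  list(cfg = cfg, coh = coh, d = d, ras = ras)
}

test_that("noiseless RAS correlates perfectly with true pooled frequencies", {
  fx <- truth_fixture()
  tc <- ras_truth_correlation(fx$ras, fx$coh, fx$d)
  expect_setequal(tc$stratum, c("cases-blood", "controls-blood", "controls-buccal"))
  expect_equal(tc$r, rep(1, nrow(tc)), tolerance = 1e-9)
})

test_that("a RAS table equal to 1 - truth anticorrelates perfectly", {
  fx <- truth_fixture()
  truth <- pool_frequencies(fx$d, fx$coh)
  anti <- manual_ras(1 - truth)
  tc <- ras_truth_correlation(anti, fx$coh, fx$d)
  expect_equal(tc$r, rep(-1, nrow(tc)), tolerance = 1e-9)
})

test_that("strata with too few SNPs are reported as not computable", {
  fx <- truth_fixture()
  expect_message(
    tc <- ras_truth_correlation(fx$ras, fx$coh, fx$d,
                                snp_subset = c("snp00001", "snp00002")),
    "not computable")
  expect_true(all(is.na(tc$r)))
})

test_that("truth correlation is invariant to increasing affine transforms of RAS", {
  fx <- truth_fixture(noise_cv = 0.1)
  tc1 <- ras_truth_correlation(fx$ras, fx$coh, fx$d)
  shifted <- fx$ras
  shifted$ras <- 0.1 + 0.5 * shifted$ras
  class(shifted) <- class(fx$ras)
  tc2 <- ras_truth_correlation(shifted, fx$coh, fx$d)
  expect_equal(tc1$r, tc2$r, tolerance = 1e-12)
})

test_that("a perfect estimator gives ratio-of-ratios exactly 1 with zero SD", {
  fx <- truth_fixture()
  truth <- pool_frequencies(fx$d, fx$coh)
  perfect <- manual_ras(truth)
  ror <- ratio_of_ratios(perfect, fx$coh, fx$d)
  expect_equal(ror$mean, rep(1, nrow(ror)), tolerance = 1e-12)
  expect_equal(ror$sd, rep(0, nrow(ror)), tolerance = 1e-12)
  expect_equal(ror$pct_within_1sd, rep(100, nrow(ror)))
})

test_that("ratio-of-ratios matches the brute-force oracle and guards denominators", {
  fx <- truth_fixture(noise_cv = 0.1)
  ror <- ratio_of_ratios(fx$ras, fx$coh, fx$d)
  m <- poolmap:::ras_matrix(fx$ras)
  truth <- pool_frequencies(fx$d, fx$coh)
  pt <- fx$d$pool_table
  cases <- pt$pool_id[pt$phenotype == "case"]
  ctrls <- pt$pool_id[pt$phenotype == "control"]
  o <- oracle_ror(colMeans(truth[ctrls, colnames(m)]),
                  colMeans(truth[cases, colnames(m)]),
                  colMeans(m[ctrls, ]), colMeans(m[cases, ]))
  row <- ror[ror$stratum == "all-controls", ]
  expect_equal(row$mean, o$mean, tolerance = 1e-12)
  expect_equal(row$sd, o$sd, tolerance = 1e-12)
  expect_equal(row$pct_within_1sd, o$pct, tolerance = 1e-12)
  expect_identical(row$n_snps, o$n)

  # a SNP whose case-side RAS collapses below epsilon is excluded and counted
  broken <- fx$ras
  snp1 <- broken$snp_id == "snp00001"
  broken$ras[snp1 & grepl("case", ras_pool_pheno(broken, fx$d))] <- 0
  class(broken) <- class(fx$ras)
  ror2 <- ratio_of_ratios(broken, fx$coh, fx$d)
  expect_identical(ror2$n_excluded[ror2$stratum == "all-controls"],
                   row$n_excluded + 1L)
})

test_that("the percent-within-1-SD statistic ignores SNP ordering", {
  fx <- truth_fixture(noise_cv = 0.1)
  snps <- fx$coh$snp_table$snp_id
  a <- ratio_of_ratios(fx$ras, fx$coh, fx$d, snp_subset = snps)
  b <- ratio_of_ratios(fx$ras, fx$coh, fx$d, snp_subset = rev(snps))
  expect_equal(a, b)
})

test_that("follow-up subset takes top hits first, then a deterministic random filler", {
  fx <- scan_fixture_for_followup()
  subset <- select_followup_snps(fx$gwas, n = 6, seed = 3)
  expect_length(subset, 6)
  expect_identical(subset[1], fx$gwas$snp_id[1])
  expect_true(all(fx$gwas$genomewide_significant[match(subset[1], fx$gwas$snp_id)]))
  expect_identical(select_followup_snps(fx$gwas, n = 6, seed = 3), subset)
  expect_false(any(subset %in%
                     fx$gwas$snp_id[fx$gwas$excluded_by_maf]))
})

test_that("validate_pools bundles all three analyses", {
  cfg <- test_config(n_cases = 192, n_controls = 192, n_snps = 40,
                     control_blood_fraction = 0.5, n_technical_replicates = 2,
                     seed = 15)
  coh <- simulate_cohort(cfg)
  d <- build_pools(coh, cfg)
  ras <- allelotype(simulate_intensities(d, coh, cfg), "pm_only")
  gwas <- run_scan(ras, d, maf_threshold = 0)
  val <- validate_pools(ras, coh, d, gwas, subset_size = 20)
  expect_s3_class(val, "snpmap_validation")
  expect_identical(nrow(val$technical), 2L)
  expect_length(val$followup_snps, 20)
  expect_true(all(val$ratio_of_ratios$n_snps <= 20))
  expect_output(print(val), "ratio of ratios")
})
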