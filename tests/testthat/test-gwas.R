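test_that("MAF is the folded mean RAS across hybridizations", {
  m <- matrix(c(0.5, 0.5, 0.5, 0.97, 0.96, 0.98, 0.1, 0.2, 0.3), nrow = 3,
              dimnames = list(paste0("p", 1:3), c("sA", "sB", "sC")))
  ras <- manual_ras(m)
  expect_equal(estimate_maf(ras, "sA"), 0.5)
  expect_equal(estimate_maf(ras, "sB"), 1 - 0.97, tolerance = 1e-12)
  expect_equal(estimate_maf(ras, "sC"), 0.2)
  expect_error(estimate_maf(ras, "nope"), "unknown SNP")
  ras$ras[ras$snp_id == "sA"] <- NA
  expect_warning(v <- estimate_maf(ras, "sA"), "missing")
  expect_true(is.na(v))
})

test_that("pool t-test agrees with stats::t.test to 1e-10 on 100 random instances", {
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- runif(n1); y <- runif(n2)
    ours <- pool_t_test(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    w <- pool_t_test(x, y, welch = TRUE)
    refw <- stats::t.test(x, y)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
    expect_equal(w$p, refw$p.value, tolerance = 1e-10)
  }
  # and with the hand-coded textbook form
  o <- oracle_student_t(c(0.60, 0.62, 0.58), c(0.50, 0.52, 0.48))
  ours <- pool_t_test(c(0.60, 0.62, 0.58), c(0.50, 0.52, 0.48))
  expect_equal(ours$t, o$t, tolerance = 1e-12)
  expect_equal(ours$p, o$p, tolerance = 1e-12)
})

test_that("t is antisymmetric under group relabeling; degenerate cases are defined", {
  x <- c(0.6, 0.65, 0.7); y <- c(0.5, 0.45, 0.55)
  a <- pool_t_test(x, y); b <- pool_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  same <- pool_t_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  expect_warning(deg <- pool_t_test(c(0.6, 0.6), c(0.4, 0.4)), "zero pooled variance")
  expect_identical(deg$p, .Machine$double.xmin)
  expect_error(pool_t_test(0.5, c(0.4, 0.5)), "at least 2 pools")
})

test_that("run_scan matches per-SNP pool_t_test and is sorted by p", {
  fx <- scan_fixture()
  res <- run_scan(fx$ras, fx$design, maf_threshold = 0)
  expect_false(is.unsorted(res$p_value))
  expect_identical(res$df, rep(8, 12))
  m <- matrix(fx$ras$ras, nrow = 10, dimnames = list(unique(fx$ras$pool_id), NULL))
  for (i in sample(12, 4)) {
    snp <- sprintf("s%03d", i)
    ref <- pool_t_test(m[1:5, i], m[6:10, i])
    row <- res[res$snp_id == snp, ]
    expect_equal(row$t_statistic, ref$t, tolerance = 1e-12)
    expect_equal(row$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("MAF exclusion removes rare SNPs from significance flagging", {
  m <- matrix(c(0.97, 0.98, 0.96, 0.975, 0.5, 0.52, 0.6, 0.63), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), c("rare", "common")))
  design <- manual_design(list(a = "i1", b = "i2", c = "i3", d = "i4"),
                          phenotype = c("case", "case", "control", "control"))
  res <- run_scan(manual_ras(m), design, maf_threshold = 0.05)
  expect_true(res$excluded_by_maf[res$snp_id == "rare"])
  expect_false(res$excluded_by_maf[res$snp_id == "common"])
  expect_false(res$genomewide_significant[res$snp_id == "rare"])
  res0 <- run_scan(manual_ras(m), design, maf_threshold = 0)
  expect_false(any(res0$excluded_by_maf))
})

test_that("an extreme frequency difference is flagged genome-wide significant", {
  set.seed(9)
  n <- 6
  m <- cbind(hit = c(rnorm(n, 0.8, 0.005), rnorm(n, 0.2, 0.005)),
             null = runif(2 * n, 0.4, 0.6))
  rownames(m) <- c(sprintf("ca%d", 1:n), sprintf("co%d", 1:n))
  design <- manual_design(setNames(as.list(paste0("i", 1:(2 * n))), rownames(m)),
                          phenotype = rep(c("case", "control"), each = n))
  res <- run_scan(manual_ras(m), design)
  expect_true(res$genomewide_significant[res$snp_id == "hit"])
  expect_false(res$genomewide_significant[res$snp_id == "null"])
  expect_identical(res$snp_id[1], "hit")
})

test_that("technical replicates collapse to one observation per pool", {
  m <- matrix(runif(4 * 6, 0.3, 0.7), nrow = 4,
              dimnames = list(c("ca1", "ca2", "co1", "co2"), paste0("s", 1:6)))
  ras1 <- manual_ras(m)
  # duplicate every pool's array with a shifted remeasurement
  ras2 <- ras1
  ras2$array_id <- sub("arr1", "arr2", ras2$array_id)
  ras2$ras <- pmin(ras2$ras + 0.01, 1)
  both <- rbind(ras1, ras2)
  attributes(both)$mode <- "pm_only"
  class(both) <- c("ras_table", "data.frame")
  design <- manual_design(list(ca1 = "i1", ca2 = "i2", co1 = "i3", co2 = "i4"),
                          phenotype = c("case", "case", "control", "control"))
  res <- run_scan(both, design, maf_threshold = 0)
  expect_identical(res$df, rep(2, 6))  # pools, not arrays, set the df
  avg <- (m + pmin(m + 0.01, 1)) / 2
  ref <- run_scan(manual_ras(avg), design, maf_threshold = 0)
  expect_equal(res$t_statistic, ref$t_statistic, tolerance = 1e-12)
})

test_that("scans are deterministic and refuse underpowered designs", {
  fx <- scan_fixture(seed = 2)
  expect_identical(run_scan(fx$ras, fx$design), run_scan(fx$ras, fx$design))
  tiny <- scan_fixture(n_case = 1, n_control = 3)
  expect_error(run_scan(tiny$ras, tiny$design), "at least 2")
})
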