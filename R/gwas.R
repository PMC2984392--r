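#' Estimate a SNP's minor allele frequency from RAS scores
#'
#' The pooled frequency estimate is the mean RAS across all hybridizations
#' of the SNP, folded at 0.5: `min(f, 1 - f)`.
#'
#' @param ras A `ras_table`.
#' @param snp_id SNP identifier present in the table.
#' @return Estimated MAF in [0, 0.5]; `NA` (with a warning) if every entry
#'   for the SNP is missing.
#' @export
estimate_maf <- function(ras, snp_id) {
  stopifnot(inherits(ras, "ras_table"))
  v <- ras$ras[ras$snp_id == snp_id]
  if (length(v) == 0L) stop("unknown SNP: ", snp_id, call. = FALSE)
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("SNP ", snp_id, ": all RAS entries missing; MAF not estimable")
    return(NA_real_)
  }
  f <- mean(v)
  min(f, 1 - f)
}

#' Pool-level two-sample Student's t-test
#'
#' Independent two-sample t-test comparing case-pool and control-pool RAS
#' scores for one SNP: pooled-variance (Student) by default, with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p-value; optionally
#' Welch's unequal-variance form.
#'
#' @param case_ras,control_ras Numeric RAS values, one per pool (at least
#'   two each).
#' @param welch Use the Welch-Satterthwaite correction instead of the
#'   pooled variance.
#' @return List with elements `t`, `df`, `p`.
#' @examples
#' pool_t_test(c(0.60, 0.62, 0.58), c(0.50, 0.52, 0.48))
#' @export
pool_t_test <- function(case_ras, control_ras, welch = FALSE) {
  case_ras <- case_ras[!is.na(case_ras)]
  control_ras <- control_ras[!is.na(control_ras)]
  n1 <- length(case_ras); n2 <- length(control_ras)
  if (n1 < 2L || n2 < 2L)
    stop("t-test undefined: need at least 2 pools per group (got ",
         n1, " and ", n2, ")", call. = FALSE)
  m1 <- mean(case_ras); m2 <- mean(control_ras)
  v1 <- stats::var(case_ras); v2 <- stats::var(control_ras)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; reporting smallest positive p")
    return(list(t = sign(m1 - m2) * Inf, df = df, p = .Machine$double.xmin))
  }
  t <- (m1 - m2) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Genome scan of case vs control pools
#'
#' Runs the pool-level association scan: technical replicate arrays are
#' averaged into one RAS value per pool, each SNP is tested with an
#' independent two-sample Student's t-test between case pools and control
#' pools (vectorized pooled-variance form across all SNPs), rare SNPs with
#' estimated minor allele frequency below `maf_threshold` are excluded, and
#' surviving SNPs with `p <= alpha_gw` are flagged genome-wide significant.
#'
#' @param ras A `ras_table` covering case and control pools.
#' @param design The `pool_design` identifying each pool's phenotype.
#' @param maf_threshold Exclude SNPs with estimated MAF below this (0.05 by
#'   default; 0 disables the exclusion).
#' @param alpha_gw Genome-wide significance threshold on the unadjusted
#'   p-value (default 7.2e-8).
#' @param welch Use Welch's t-test instead of the pooled-variance Student
#'   form.
#' @return A data.frame of class `pool_gwas`, sorted by p-value, with
#'   columns `snp_id`, `mean_ras_cases`, `mean_ras_controls`, `t_statistic`,
#'   `df`, `p_value`, `estimated_maf`, `excluded_by_maf`,
#'   `genomewide_significant`.
#' @export
run_scan <- function(ras, design, maf_threshold = 0.05, alpha_gw = 7.2e-8,
                     welch = FALSE) {
  stopifnot(inherits(ras, "ras_table"), inherits(design, "pool_design"))
  m <- ras_matrix(ras)
  pheno <- design$pool_table$phenotype[match(rownames(m), design$pool_table$pool_id)]
  if (anyNA(pheno))
    stop("pools missing from design: ",
         paste(rownames(m)[is.na(pheno)], collapse = ", "), call. = FALSE)
  ca <- m[pheno == "case", , drop = FALSE]
  co <- m[pheno == "control", , drop = FALSE]
  if (nrow(ca) < 2L || nrow(co) < 2L)
    stop("scan undefined: need at least 2 case pools and 2 control pools",
         call. = FALSE)

  n1 <- colSums(!is.na(ca)); n2 <- colSums(!is.na(co))
  m1 <- colMeans(ca, na.rm = TRUE); m2 <- colMeans(co, na.rm = TRUE)
  v1 <- col_var(ca, m1, n1); v2 <- col_var(co, m2, n2)
  testable <- n1 >= 2L & n2 >= 2L
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)
  }
  tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df),
              ifelse(m1 == m2, 1, .Machine$double.xmin))
  if (any(testable & se2 == 0 & m1 != m2))
    warning("zero pooled variance with unequal means for ",
            sum(testable & se2 == 0 & m1 != m2),
            " SNP(s); reporting smallest positive p")
  tt[!testable] <- NA_real_; p[!testable] <- NA_real_

  n_all <- colSums(!is.na(m))
  f_hat <- colMeans(m, na.rm = TRUE)
  maf <- pmin(f_hat, 1 - f_hat)
  maf[n_all == 0L] <- NA_real_
  if (any(n_all == 0L))
    warning(sum(n_all == 0L), " SNP(s) with no scoreable RAS entries skipped")
  excl <- !is.na(maf) & maf < maf_threshold

  res <- data.frame(
    snp_id = colnames(m),
    mean_ras_cases = m1, mean_ras_controls = m2,
    t_statistic = tt, df = df, p_value = p,
    estimated_maf = maf,
    excluded_by_maf = excl,
    genomewide_significant = !excl & !is.na(p) & p <= alpha_gw,
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_value, method = "radix", na.last = TRUE), ]
  rownames(res) <- NULL
  structure(res,
            n_case_pools = nrow(ca), n_control_pools = nrow(co),
            maf_threshold = maf_threshold, alpha_gw = alpha_gw, welch = welch,
            class = c("pool_gwas", "data.frame"))
}

# column-wise sample variance given precomputed means and counts (NA-aware)
col_var <- function(x, means, n) {
  d <- sweep(x, 2, means)
  colSums(d * d, na.rm = TRUE) / pmax(n - 1, 1)
}

#' @export
print.pool_gwas <- function(x, n = 10, ...) {
  cat(sprintf("Pool-level GWAS: %d SNPs, %d case vs %d control pools\n",
              nrow(x), attr(x, "n_case_pools"), attr(x, "n_control_pools")))
  cat(sprintf("  MAF < %g excluded: %d; genome-wide significant (p <= %g): %d\n",
              attr(x, "maf_threshold"), sum(x$excluded_by_maf),
              attr(x, "alpha_gw"), sum(x$genomewide_significant)))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
summary.pool_gwas <- function(object, ...) {
  out <- list(
    n_snps = nrow(object),
    n_case_pools = attr(object, "n_case_pools"),
    n_control_pools = attr(object, "n_control_pools"),
    n_excluded_maf = sum(object$excluded_by_maf),
    n_genomewide_significant = sum(object$genomewide_significant),
    alpha_gw = attr(object, "alpha_gw"),
    maf_threshold = attr(object, "maf_threshold"),
    top = utils::head(as.data.frame(object), 5))
  class(out) <- "summary.pool_gwas"
  out
}

#' @export
print.summary.pool_gwas <- function(x, ...) {
  cat(sprintf(paste0("Pool GWAS summary: %d SNPs (%d case / %d control pools)\n",
                     "  excluded at MAF < %g: %d\n",
                     "  genome-wide significant at p <= %g: %d\n"),
              x$n_snps, x$n_case_pools, x$n_control_pools,
              x$maf_threshold, x$n_excluded_maf, x$alpha_gw,
              x$n_genomewide_significant))
  cat("Top SNPs:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' Manhattan-style plot of a pool GWAS
#'
#' @param x A `pool_gwas` result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pool_gwas <- function(x, ...) {
  ord <- order(x$snp_id)
  p <- x$p_value[ord]
  graphics::plot(seq_along(p), -log10(p),
                 xlab = "SNP index", ylab = expression(-log[10](p)),
                 pch = 20, col = ifelse(x$excluded_by_maf[ord], "grey70", "grey30"),
                 ...)
  graphics::abline(h = -log10(attr(x, "alpha_gw")), col = "red", lty = 2)
  invisible(x)
}
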