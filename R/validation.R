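#' Replicate-correlation quality control
#'
#' Technical replicates are the same pool hybridized on two arrays; their
#' RAS vectors should agree closely, and the pairwise Pearson correlation
#' per duplicated pool is the QC statistic. Biological replicates are
#' distinct pools drawn from the same phenotypic cell; the statistic is the
#' mean pairwise correlation among the replicate-collapsed RAS vectors of
#' each replicate group.
#'
#' @param ras A `ras_table`.
#' @param grouping `"technical"` or `"biological"`.
#' @param design Required for `grouping = "biological"`: the `pool_design`
#'   carrying replicate groups.
#' @return For technical grouping, a data.frame `pool_id`, `array_1`,
#'   `array_2`, `r`; for biological grouping, a data.frame
#'   `replicate_group`, `n_pools`, `mean_r`.
#' @export
replicate_correlation <- function(ras, grouping = c("technical", "biological"),
                                  design = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(ras, "ras_table"))
  if (grouping == "technical") {
    rows <- list()
    for (pid in unique(ras$pool_id)) {
      arrs <- unique(ras$array_id[ras$pool_id == pid])
      if (length(arrs) < 2L) next
      vecs <- lapply(arrs, function(a) {
        sub <- ras[ras$array_id == a, ]
        stats::setNames(sub$ras, sub$snp_id)
      })
      for (i in seq_len(length(arrs) - 1L)) for (j in (i + 1L):length(arrs)) {
        r <- safe_pearson(vecs[[i]][names(vecs[[j]])], vecs[[j]])
        if (is.na(r)) {
          warning("constant or unscoreable RAS vector; skipping pair ",
                  arrs[i], " / ", arrs[j])
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pool_id = pid, array_1 = arrs[i], array_2 = arrs[j], r = r,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L)
      return(data.frame(pool_id = character(), array_1 = character(),
                        array_2 = character(), r = numeric()))
    return(do.call(rbind, rows))
  }
  if (is.null(design))
    stop("biological replicate correlation requires the pool design", call. = FALSE)
  m <- ras_matrix(ras)
  pt <- design$pool_table
  rows <- list()
  for (g in unique(stats::na.omit(pt$replicate_group))) {
    pools <- intersect(pt$pool_id[!is.na(pt$replicate_group) &
                                    pt$replicate_group == g], rownames(m))
    if (length(pools) < 2L) next
    rs <- c()
    for (i in seq_len(length(pools) - 1L)) for (j in (i + 1L):length(pools)) {
      r <- safe_pearson(m[pools[i], ], m[pools[j], ])
      if (is.na(r)) {
        warning("constant RAS vector; skipping pair ", pools[i], " / ", pools[j])
        next
      }
      rs <- c(rs, r)
    }
    if (length(rs))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_group = g, n_pools = length(pools), mean_r = mean(rs),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(replicate_group = character(), n_pools = integer(),
                      mean_r = numeric()))
  do.call(rbind, rows)
}

# Pearson r over complete pairs; NA when undefined (constant vector)
safe_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# phenotype/DNA-source strata among pools, labelled "cases-blood" etc.
pool_strata <- function(pt) {
  lab <- paste0(ifelse(pt$phenotype == "case", "cases", "controls"),
                "-", pt$dna_source)
  split(pt$pool_id, lab)
}

#' Correlation of RAS estimates with true pooled allele frequencies
#'
#' For each phenotype x DNA-source stratum, correlates the SNP-level mean
#' RAS (across the stratum's pools) with the "real" allele frequency the
#' pools' members carry (the mean weighted pooled frequency from the
#' genotypes). This is the validation a pooling study performs against
#' confirmatory individual genotyping, and the contrast between blood-DNA
#' and buccal-DNA strata measures how DNA quality degrades allelotyping.
#'
#' @param ras A `ras_table`.
#' @param cohort The simulated cohort (source of true genotypes).
#' @param design The `pool_design`.
#' @param snp_subset Optional character vector restricting the SNPs used.
#' @param min_snps Minimum SNPs with both values for a stratum to be
#'   computable (default 3).
#' @return data.frame with `stratum`, `n_pools`, `n_snps`, `r` (`NA` when
#'   not computable).
#' @export
ras_truth_correlation <- function(ras, cohort, design, snp_subset = NULL,
                                  min_snps = 3L) {
  stopifnot(inherits(ras, "ras_table"), inherits(cohort, "snpmap_cohort"),
            inherits(design, "pool_design"))
  m <- ras_matrix(ras)
  truth <- pool_frequencies(design, cohort)
  snps <- intersect(colnames(m), colnames(truth))
  if (!is.null(snp_subset)) snps <- intersect(snps, snp_subset)
  strata <- pool_strata(design$pool_table)
  rows <- lapply(names(strata), function(s) {
    pools <- intersect(strata[[s]], rownames(m))
    est <- colMeans(m[pools, snps, drop = FALSE], na.rm = TRUE)
    tru <- colMeans(truth[pools, snps, drop = FALSE])
    ok <- !is.na(est) & !is.na(tru)
    r <- if (sum(ok) >= min_snps) safe_pearson(est[ok], tru[ok]) else NA_real_
    if (sum(ok) < min_snps)
      message("stratum ", s, ": fewer than ", min_snps,
              " SNPs with both values; correlation not computable")
    data.frame(stratum = s, n_pools = length(pools), n_snps = sum(ok), r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ratio-of-ratios concordance between pooled and true frequency ratios
#'
#' For each SNP the control/case ratio of true mean allele frequencies is
#' divided by the control/case ratio of mean pool RAS scores:
#' \deqn{R = (\bar f_{ctrl} / \bar f_{case}) / (\overline{RAS}_{ctrl} /
#' \overline{RAS}_{case})}
#' A value of 1 means the pools estimate the group frequency ratio
#' perfectly even if absolute RAS scores are biased. Reported per control
#' stratum (all controls, blood controls, buccal controls; cases are always
#' the full case-pool set): the mean of `R`, its sample SD and the
#' percentage of SNPs within one SD of the mean. SNPs whose case-side
#' frequency or control-side RAS falls below `epsilon` are excluded from
#' the statistic.
#'
#' @param ras A `ras_table`.
#' @param cohort The simulated cohort.
#' @param design The `pool_design`.
#' @param snp_subset Optional character vector of SNPs (e.g. the follow-up
#'   set from [select_followup_snps()]); default all SNPs.
#' @param epsilon Denominator guard (default 1e-6).
#' @return data.frame with `stratum`, `mean`, `sd`, `pct_within_1sd`,
#'   `n_snps`, `n_excluded`.
#' @export
ratio_of_ratios <- function(ras, cohort, design, snp_subset = NULL,
                            epsilon = 1e-6) {
  stopifnot(inherits(ras, "ras_table"), inherits(cohort, "snpmap_cohort"),
            inherits(design, "pool_design"))
  m <- ras_matrix(ras)
  truth <- pool_frequencies(design, cohort)
  snps <- intersect(colnames(m), colnames(truth))
  if (!is.null(snp_subset)) snps <- intersect(snps, snp_subset)
  pt <- design$pool_table
  case_pools <- intersect(pt$pool_id[pt$phenotype == "case"], rownames(m))
  ctrl_sets <- list("all-controls" = pt$pool_id[pt$phenotype == "control"])
  for (src in unique(pt$dna_source[pt$phenotype == "control"]))
    ctrl_sets[[paste0("controls-", src)]] <-
      pt$pool_id[pt$phenotype == "control" & pt$dna_source == src]

  f_case <- colMeans(truth[case_pools, snps, drop = FALSE])
  r_case <- colMeans(m[case_pools, snps, drop = FALSE], na.rm = TRUE)
  rows <- lapply(names(ctrl_sets), function(s) {
    pools <- intersect(ctrl_sets[[s]], rownames(m))
    f_ctrl <- colMeans(truth[pools, snps, drop = FALSE])
    r_ctrl <- colMeans(m[pools, snps, drop = FALSE], na.rm = TRUE)
    ok <- !is.na(r_case) & !is.na(r_ctrl) &
      f_case > epsilon & r_case > epsilon & r_ctrl > epsilon & f_ctrl > epsilon
    R <- (f_ctrl[ok] / f_case[ok]) / (r_ctrl[ok] / r_case[ok])
    sm <- ror_summary(R)
    data.frame(stratum = s, mean = sm$mean, sd = sm$sd,
               pct_within_1sd = sm$pct, n_snps = sm$n,
               n_excluded = length(snps) - sm$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# mean, sample SD and percent of values within one SD of the mean
ror_summary <- function(R) {
  n <- length(R)
  if (n >= 2L) {
    mu <- mean(R); sdev <- stats::sd(R)
    pct <- 100 * mean(abs(R - mu) <= sdev)
  } else if (n == 1L) {
    mu <- R; sdev <- NA_real_; pct <- NA_real_
  } else {
    mu <- NA_real_; sdev <- NA_real_; pct <- NA_real_
  }
  list(mean = mu, sd = sdev, pct = pct, n = n)
}

#' Select the follow-up SNP subset from a scan
#'
#' Emulates picking "top-hit" SNPs for confirmatory individual genotyping:
#' the top-ranked non-excluded SNPs by p-value, padded with a random draw
#' from the remaining non-excluded SNPs when the scan yields fewer
#' significant hits than requested.
#'
#' @param gwas A `pool_gwas` result.
#' @param n Subset size (default 110).
#' @param seed Seed for the random filler.
#' @return Character vector of SNP identifiers, length `min(n, available)`.
#' @export
select_followup_snps <- function(gwas, n = 110L, seed = 1L) {
  stopifnot(inherits(gwas, "pool_gwas"))
  pool <- gwas[!gwas$excluded_by_maf & !is.na(gwas$p_value), ]
  n_top <- min(sum(pool$genomewide_significant), n)
  top <- pool$snp_id[seq_len(n_top)]  # already sorted by p
  rest <- setdiff(pool$snp_id, top)
  n_fill <- min(n - n_top, length(rest))
  fill <- if (n_fill > 0)
    with_stage_seed(seed, "followup", sample(rest, n_fill)) else character(0)
  c(top, fill)
}

#' Full validation report for a pooled allelotyping study
#'
#' Bundles the three validation analyses: technical and biological
#' replicate correlations, RAS-versus-truth correlation per DNA-source
#' stratum, and the ratio-of-ratios concordance statistic on a follow-up
#' SNP subset.
#'
#' @param ras A `ras_table`.
#' @param cohort The simulated cohort.
#' @param design The `pool_design`.
#' @param gwas Optional `pool_gwas` used to pick the follow-up subset; when
#'   omitted the ratio-of-ratios uses all SNPs.
#' @param subset_size Follow-up subset size (default 110).
#' @param epsilon Ratio denominator guard.
#' @param seed Seed for the follow-up filler draw.
#' @return List of class `snpmap_validation` with elements `technical`,
#'   `biological`, `truth_correlation`, `ratio_of_ratios`, `followup_snps`.
#' @export
validate_pools <- function(ras, cohort, design, gwas = NULL,
                           subset_size = 110L, epsilon = 1e-6, seed = 1L) {
  subset <- if (!is.null(gwas)) select_followup_snps(gwas, subset_size, seed)
            else NULL
  structure(list(
    technical = replicate_correlation(ras, "technical"),
    biological = replicate_correlation(ras, "biological", design),
    truth_correlation = ras_truth_correlation(ras, cohort, design),
    ratio_of_ratios = ratio_of_ratios(ras, cohort, design, subset, epsilon),
    followup_snps = subset
  ), class = "snpmap_validation")
}

#' @export
print.snpmap_validation <- function(x, ...) {
  cat("SNP-MaP validation report\n")
  cat("-- technical replicate correlations --\n")
  if (nrow(x$technical)) print(x$technical, digits = 4) else cat("  (none)\n")
  cat("-- biological replicate mean correlations --\n")
  if (nrow(x$biological)) print(x$biological, digits = 4) else cat("  (none)\n")
  cat("-- RAS vs true allele frequency --\n")
  print(x$truth_correlation, digits = 4)
  cat("-- ratio of ratios (control/case, truth over RAS) --\n")
  print(x$ratio_of_ratios, digits = 4)
  invisible(x)
}

#' Scatter plots of RAS estimates against true allele frequencies
#'
#' One panel per phenotype x DNA-source stratum: SNP-level mean RAS against
#' the true pooled frequency, with the identity line. The compression of
#' the RAS axis toward 0.5 in PM-only data is the expected background
#' artefact.
#'
#' @param x A `snpmap_validation` report (plotting needs the original data,
#'   so pass them through `ras`, `cohort`, `design`).
#' @param ras,cohort,design The objects the report was built from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.snpmap_validation <- function(x, ras, cohort, design, ...) {
  m <- ras_matrix(ras)
  truth <- pool_frequencies(design, cohort)
  strata <- pool_strata(design$pool_table)
  old <- graphics::par(mfrow = c(1, length(strata)))
  on.exit(graphics::par(old))
  for (s in names(strata)) {
    pools <- intersect(strata[[s]], rownames(m))
    est <- colMeans(m[pools, , drop = FALSE], na.rm = TRUE)
    tru <- colMeans(truth[pools, colnames(m), drop = FALSE])
    graphics::plot(tru, est, xlim = c(0, 1), ylim = c(0, 1), pch = 20,
                   xlab = "true allele frequency", ylab = "mean RAS",
                   main = s, ...)
    graphics::abline(0, 1, col = "red", lty = 2)
  }
  invisible(x)
}
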