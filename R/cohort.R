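#' Simulate a case-control cohort with Hardy-Weinberg genotypes
#'
#' Draws a cohort of unrelated individuals with independent biallelic SNPs.
#' Control allele-A frequencies come from the configured uniform minor-allele
#' spectrum (randomly flipped to `1 - f` so the measured allele is minor or
#' major with equal probability by default); genotypes are Hardy-Weinberg
#' binomial draws. For effect SNPs the case frequency is shifted at the
#' allele level by the configured odds ratio,
#' `f_case = OR * f / (OR * f + 1 - f)`; non-effect SNPs share the control
#' frequency. Sex, covariate stratum and DNA source (blood or buccal) are
#' assigned independently per configured proportions.
#'
#' @param config A [snpmap_config()] object.
#' @return An object of class `snpmap_cohort`: a list with
#'   `individuals` (data.frame: `id`, `phenotype`, `sex`, `stratum`,
#'   `dna_source`), `genotypes` (integer matrix individuals x SNPs of
#'   allele-A dosages in 0/1/2, dimnames set) and `snp_table` (data.frame:
#'   `snp_id`, `freq_a_control`, `freq_a_case`, `true_maf_control`,
#'   `is_effect`).
#' @examples
#' coh <- simulate_cohort(snpmap_config(n_cases = 20, n_controls = 20,
#'                                      n_snps = 5, seed = 7))
#' table(coh$individuals$phenotype)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "snpmap_config"))
  with_stage_seed(config$seed, "cohort", {
    n_snps <- config$n_snps
    snp_id <- sprintf("snp%05d", seq_len(n_snps))

    f <- stats::runif(n_snps, config$maf_distribution[1], config$maf_distribution[2])
    flip <- stats::runif(n_snps) < config$allele_flip_prob
    f[flip] <- 1 - f[flip]

    is_effect <- rep(FALSE, n_snps)
    if (config$n_effect_snps > 0)
      is_effect[sample.int(n_snps, config$n_effect_snps)] <- TRUE
    or <- config$effect_odds_ratio
    f_case <- ifelse(is_effect, or * f / (or * f + 1 - f), f)

    n_ca <- config$n_cases
    n_co <- config$n_controls
    n <- n_ca + n_co
    phenotype <- rep(c("case", "control"), c(n_ca, n_co))
    individuals <- data.frame(
      id = sprintf("ind%05d", seq_len(n)),
      phenotype = phenotype,
      sex = ifelse(stats::runif(n) < config$female_fraction, "female", "male"),
      stratum = paste0("bmi", sample.int(3, n, replace = TRUE,
                                         prob = config$stratum_probs)),
      dna_source = ifelse(
        stats::runif(n) < ifelse(phenotype == "case",
                                 config$case_blood_fraction,
                                 config$control_blood_fraction),
        "blood", "buccal"),
      stringsAsFactors = FALSE
    )

    g_case <- stats::rbinom(n_ca * n_snps, 2L, rep(f_case, each = n_ca))
    g_ctrl <- stats::rbinom(n_co * n_snps, 2L, rep(f, each = n_co))
    genotypes <- matrix(0L, nrow = n, ncol = n_snps,
                        dimnames = list(individuals$id, snp_id))
    genotypes[seq_len(n_ca), ] <- g_case
    genotypes[n_ca + seq_len(n_co), ] <- g_ctrl

    structure(list(
      individuals = individuals,
      genotypes = genotypes,
      snp_table = data.frame(
        snp_id = snp_id,
        freq_a_control = f,
        freq_a_case = f_case,
        true_maf_control = pmin(f, 1 - f),
        is_effect = is_effect,
        stringsAsFactors = FALSE
      )
    ), class = "snpmap_cohort")
  })
}

#' @export
print.snpmap_cohort <- function(x, ...) {
  tab <- table(x$individuals$phenotype, x$individuals$dna_source)
  cat(sprintf("SNP-MaP cohort: %d individuals x %d SNPs (%d effect SNPs)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$snp_table$is_effect)))
  print(tab)
  invisible(x)
}
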