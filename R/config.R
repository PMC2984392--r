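#' Simulation configuration for a pooled-DNA SNP microarray study
#'
#' Builds and validates the parameter set that drives the synthetic cohort,
#' pool construction and probe-intensity generators. Defaults emulate the
#' study conditions of a pooled case-control scan on a high-density array
#' without mismatch probes: ~1,400 cases and ~1,300 controls pooled into
#' groups of about 48 individuals stratified by phenotype, sex and a 3-level
#' covariate (a body-mass-index band), 6-8 probes per SNP, three pools
#' hybridized in duplicate, cases contributing blood DNA and controls a
#' blood/buccal mixture.
#'
#' @param n_cases,n_controls Number of case and control individuals.
#' @param n_snps Number of independent SNPs to simulate.
#' @param n_effect_snps Number of SNPs carrying a case-control frequency
#'   shift; must not exceed `n_snps`.
#' @param effect_odds_ratio Allele-level odds ratio applied to effect SNPs:
#'   the case allele frequency is `OR*f / (OR*f + 1 - f)` where `f` is the
#'   control frequency.
#' @param maf_distribution Length-2 numeric: uniform bounds for the control
#'   minor allele frequency, within [0.01, 0.5].
#' @param allele_flip_prob Probability that the measured (allele-A) frequency
#'   is `1 - f` rather than `f`, so RAS scores span the whole unit interval.
#' @param target_pool_size Intended number of individuals per pool.
#' @param pipetting_cv Coefficient of variation of per-individual DNA
#'   contribution around equal shares; 0 gives exactly equal weights.
#' @param probes_per_snp Integer count or length-2 range; each SNP receives a
#'   probe quartet count drawn uniformly from the range.
#' @param has_mismatch_probes If `TRUE`, mismatch (MM) channels capturing
#'   background only are simulated alongside the perfect-match channels, as
#'   on older array generations.
#' @param signal_scale Allele-specific signal intensity scale `S`.
#' @param background_level Shared additive background intensity `b`.
#' @param cross_hyb_fraction Fraction `kappa` in [0, 1) of the opposite
#'   allele's signal bleeding into each channel.
#' @param noise_cv Multiplicative measurement noise: each channel's SD is
#'   `noise_cv * noise_multiplier * channel mean`.
#' @param probe_affinity_sdlog SD (log scale) of the lognormal, unit-median
#'   per-probe affinity.
#' @param quality Named list mapping DNA source (`blood`, `buccal`) to a
#'   numeric vector `c(signal, background, noise)` of multipliers applied to
#'   the signal scale, background level and noise SD respectively.
#' @param case_blood_fraction,control_blood_fraction Probability that a case
#'   (control) individual contributes blood rather than buccal DNA.
#' @param female_fraction Probability an individual is female.
#' @param stratum_probs Length-3 probabilities of the covariate strata.
#' @param n_technical_replicates Number of pools hybridized on two arrays.
#' @param seed Integer seed; fully determines all simulation output.
#'
#' @return A validated list of class `snpmap_config`.
#' @examples
#' cfg <- snpmap_config(n_cases = 96, n_controls = 96, n_snps = 50, seed = 1)
#' cfg$target_pool_size
#' @export
snpmap_config <- function(n_cases = 1418L,
                          n_controls = 1301L,
                          n_snps = 10000L,
                          n_effect_snps = 0L,
                          effect_odds_ratio = 1,
                          maf_distribution = c(0.05, 0.5),
                          allele_flip_prob = 0.5,
                          target_pool_size = 48L,
                          pipetting_cv = 0.05,
                          probes_per_snp = c(6L, 8L),
                          has_mismatch_probes = FALSE,
                          signal_scale = 2000,
                          background_level = 200,
                          cross_hyb_fraction = 0.05,
                          noise_cv = 0.15,
                          probe_affinity_sdlog = 0.3,
                          quality = list(blood = c(signal = 1, background = 1, noise = 1),
                                         buccal = c(signal = 0.4, background = 2, noise = 2)),
                          case_blood_fraction = 1,
                          control_blood_fraction = 10 / 28,
                          female_fraction = 0.5,
                          stratum_probs = c(1, 1, 1) / 3,
                          n_technical_replicates = 3L,
                          seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_effect_snps = as.integer(n_effect_snps),
    effect_odds_ratio = effect_odds_ratio,
    maf_distribution = as.numeric(maf_distribution),
    allele_flip_prob = allele_flip_prob,
    target_pool_size = as.integer(target_pool_size),
    pipetting_cv = pipetting_cv,
    probes_per_snp = as.integer(probes_per_snp),
    has_mismatch_probes = isTRUE(has_mismatch_probes),
    signal_scale = signal_scale, background_level = background_level,
    cross_hyb_fraction = cross_hyb_fraction, noise_cv = noise_cv,
    probe_affinity_sdlog = probe_affinity_sdlog,
    quality = quality,
    case_blood_fraction = case_blood_fraction,
    control_blood_fraction = control_blood_fraction,
    female_fraction = female_fraction,
    stratum_probs = as.numeric(stratum_probs),
    n_technical_replicates = as.integer(n_technical_replicates),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "snpmap_config"
  cfg
}

# Range/shape checks; errors name the offending field.
validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid configuration: `", field, "` ", what, call. = FALSE)
  }
  count1 <- function(x) length(x) == 1L && !is.na(x) && x >= 1
  chk(count1(cfg$n_cases), "n_cases", "must be a positive count")
  chk(count1(cfg$n_controls), "n_controls", "must be a positive count")
  chk(count1(cfg$n_snps), "n_snps", "must be a positive count")
  chk(length(cfg$n_effect_snps) == 1L && cfg$n_effect_snps >= 0, "n_effect_snps",
      "must be a nonnegative count")
  chk(cfg$n_effect_snps <= cfg$n_snps, "n_effect_snps", "must not exceed n_snps")
  chk(length(cfg$effect_odds_ratio) == 1L && cfg$effect_odds_ratio > 0,
      "effect_odds_ratio", "must be > 0")
  chk(length(cfg$maf_distribution) == 2L &&
        all(cfg$maf_distribution >= 0.01) && all(cfg$maf_distribution <= 0.5) &&
        cfg$maf_distribution[1] <= cfg$maf_distribution[2],
      "maf_distribution", "must be ordered bounds within [0.01, 0.5]")
  chk(length(cfg$allele_flip_prob) == 1L && cfg$allele_flip_prob >= 0 &&
        cfg$allele_flip_prob <= 1, "allele_flip_prob", "must be in [0, 1]")
  chk(count1(cfg$target_pool_size), "target_pool_size", "must be a positive count")
  chk(length(cfg$pipetting_cv) == 1L && cfg$pipetting_cv >= 0, "pipetting_cv",
      "must be >= 0")
  chk(length(cfg$probes_per_snp) %in% 1:2 && all(cfg$probes_per_snp >= 1),
      "probes_per_snp", "must be a count or a range of counts >= 1")
  chk(length(cfg$signal_scale) == 1L && cfg$signal_scale > 0, "signal_scale",
      "must be > 0")
  chk(length(cfg$background_level) == 1L && cfg$background_level >= 0,
      "background_level", "must be >= 0")
  chk(length(cfg$cross_hyb_fraction) == 1L && cfg$cross_hyb_fraction >= 0 &&
        cfg$cross_hyb_fraction < 1, "cross_hyb_fraction", "must be in [0, 1)")
  chk(length(cfg$noise_cv) == 1L && cfg$noise_cv >= 0, "noise_cv", "must be >= 0")
  chk(length(cfg$probe_affinity_sdlog) == 1L && cfg$probe_affinity_sdlog >= 0,
      "probe_affinity_sdlog", "must be >= 0")
  chk(is.list(cfg$quality) && all(c("blood", "buccal") %in% names(cfg$quality)),
      "quality", "must be a list with entries `blood` and `buccal`")
  for (src in names(cfg$quality)) {
    q <- cfg$quality[[src]]
    chk(length(q) == 3L && q[1] > 0 && q[1] <= 1 && q[2] >= 1 && q[3] >= 1,
        paste0("quality$", src),
        "must be c(signal, background, noise) with signal in (0,1], background >= 1, noise >= 1")
  }
  chk(length(cfg$case_blood_fraction) == 1L && cfg$case_blood_fraction >= 0 &&
        cfg$case_blood_fraction <= 1, "case_blood_fraction", "must be in [0, 1]")
  chk(length(cfg$control_blood_fraction) == 1L && cfg$control_blood_fraction >= 0 &&
        cfg$control_blood_fraction <= 1, "control_blood_fraction", "must be in [0, 1]")
  chk(length(cfg$female_fraction) == 1L && cfg$female_fraction >= 0 &&
        cfg$female_fraction <= 1, "female_fraction", "must be in [0, 1]")
  chk(length(cfg$stratum_probs) == 3L && all(cfg$stratum_probs > 0),
      "stratum_probs", "must be 3 positive weights")
  chk(length(cfg$n_technical_replicates) == 1L && cfg$n_technical_replicates >= 0,
      "n_technical_replicates", "must be a nonnegative count")
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.snpmap_config <- function(x, ...) {
  cat("SNP-MaP simulation configuration\n")
  cat(sprintf("  cohort: %d cases + %d controls, %d SNPs (%d with effect, OR = %g)\n",
              x$n_cases, x$n_controls, x$n_snps, x$n_effect_snps,
              x$effect_odds_ratio))
  cat(sprintf("  pools: target size %d, pipetting CV %g, %d technical replicate(s)\n",
              x$target_pool_size, x$pipetting_cv, x$n_technical_replicates))
  cat(sprintf("  array: %s probes/SNP, mismatch probes: %s\n",
              paste(x$probes_per_snp, collapse = "-"),
              if (x$has_mismatch_probes) "yes" else "no"))
  cat(sprintf("  signal model: S = %g, b = %g, kappa = %g, noise CV = %g\n",
              x$signal_scale, x$background_level, x$cross_hyb_fraction, x$noise_cv))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic per-stage seed derived from the top-level seed, so each
# pipeline stage has its own reproducible substream: re-running one stage
# never perturbs another stage's draws.
stage_seed <- function(seed, stage) {
  s <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(stage)) s <- (s * 131 + code) %% 2147483629
  as.integer(s + 1)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}
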