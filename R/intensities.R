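#' Simulate pool-level probe hybridization intensities
#'
#' Generates allele-A and allele-B perfect-match (PM) channel intensities
#' for every pool hybridization and probe, and mismatch (MM) channels when
#' the configured array design has them. For a pool with true weighted
#' allele-A frequency `f`, probe `j` with lognormal affinity `phi_j` and
#' DNA-source quality multipliers `(m_sig, m_bg, m_noise)`:
#'
#' \deqn{PM_A = m_{sig} S \phi_j (f + \kappa(1-f)) + m_{bg} b + \epsilon}
#' \deqn{PM_B = m_{sig} S \phi_j ((1-f) + \kappa f) + m_{bg} b + \epsilon'}
#'
#' and mismatch probes capture background only,
#' `MM = m_bg * b + epsilon''`. Every noise term is an independent zero-mean
#' normal with SD equal to `noise_cv * m_noise` times the channel mean,
#' truncated by clamping intensities at zero. Pools selected as technical
#' replicates are hybridized on two arrays: the second array redraws only
#' the measurement noise.
#'
#' @param design A [build_pools()] design.
#' @param cohort The matching [simulate_cohort()] cohort.
#' @param config The [snpmap_config()] shared by the simulation.
#' @return An object of class `intensity_matrix`: list with `arrays`
#'   (data.frame `pool_id`, `array_id`, `dna_source`), `probes` (data.frame
#'   `snp_id`, `probe_index`), `channels` (list of arrays x probes matrices
#'   `PM_A`, `PM_B` and, in mismatch designs, `MM_A`, `MM_B`) and
#'   `has_mismatch`.
#' @seealso [simulate_probe_intensities()] to drive the same signal model
#'   directly from a frequency matrix.
#' @export
simulate_intensities <- function(design, cohort, config) {
  stopifnot(inherits(design, "pool_design"), inherits(config, "snpmap_config"))
  f_pool <- pool_frequencies(design, cohort)
  with_stage_seed(config$seed, "intensities", {
    n_pools <- nrow(f_pool)
    dup <- integer(0)
    if (config$n_technical_replicates > 0)
      dup <- sort(sample.int(n_pools, min(config$n_technical_replicates, n_pools)))
    pool_idx <- c(seq_len(n_pools), dup)
    rep_no <- c(rep(1L, n_pools), rep(2L, length(dup)))
    arrays <- data.frame(
      pool_id = rownames(f_pool)[pool_idx],
      array_id = sprintf("%s_arr%d", rownames(f_pool)[pool_idx], rep_no),
      dna_source = design$pool_table$dna_source[pool_idx],
      stringsAsFactors = FALSE)
    intensity_core(f_pool[pool_idx, , drop = FALSE], arrays, config)
  })
}

#' Simulate probe intensities directly from pooled allele frequencies
#'
#' Bypasses cohort and pool construction: each row of `freqs` is treated as
#' one hybridization with known true allele-A frequencies. Useful for
#' studying the signal model in isolation (for example the pull of RAS
#' scores toward 0.5 as background grows).
#'
#' @param freqs Numeric matrix (hybridizations x SNPs) of frequencies in
#'   [0, 1]; a vector is taken as a single hybridization. Column names are
#'   used as SNP identifiers when present.
#' @param config A [snpmap_config()]; the signal-model fields and seed are
#'   used.
#' @param dna_source DNA source per hybridization (recycled), selecting the
#'   quality multipliers.
#' @return An `intensity_matrix`, as for [simulate_intensities()].
#' @export
simulate_probe_intensities <- function(freqs, config, dna_source = "blood") {
  stopifnot(inherits(config, "snpmap_config"))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  if (is.null(colnames(freqs)))
    colnames(freqs) <- sprintf("snp%05d", seq_len(ncol(freqs)))
  if (is.null(rownames(freqs)))
    rownames(freqs) <- sprintf("pool%03d", seq_len(nrow(freqs)))
  stopifnot(all(freqs >= 0 & freqs <= 1))
  dna_source <- rep_len(dna_source, nrow(freqs))
  arrays <- data.frame(pool_id = rownames(freqs),
                       array_id = paste0(rownames(freqs), "_arr1"),
                       dna_source = dna_source, stringsAsFactors = FALSE)
  with_stage_seed(config$seed, "intensities", intensity_core(freqs, arrays, config))
}

# Shared signal model. `f` is hybridizations x SNPs; `arrays` one row per
# hybridization. Draw order (probe counts, affinities, then channel noise)
# is fixed so a given stage seed yields bit-identical output.
intensity_core <- function(f, arrays, config) {
  n_arr <- nrow(arrays)
  n_snps <- ncol(f)
  ppS <- config$probes_per_snp
  n_probes <- if (length(ppS) == 1L) rep(ppS, n_snps) else
    ppS[1] + sample.int(ppS[2] - ppS[1] + 1L, n_snps, replace = TRUE) - 1L
  probes <- data.frame(
    snp_id = rep(colnames(f), n_probes),
    probe_index = sequence(n_probes),
    stringsAsFactors = FALSE)
  P <- nrow(probes)
  phi <- stats::rlnorm(P, meanlog = 0, sdlog = config$probe_affinity_sdlog)

  qual <- do.call(rbind, config$quality[arrays$dna_source])
  m_sig <- qual[, 1]; m_bg <- qual[, 2]; m_noise <- qual[, 3]

  fp <- f[, rep(seq_len(n_snps), n_probes), drop = FALSE]  # arrays x probes
  kap <- config$cross_hyb_fraction
  gain <- outer(m_sig * config$signal_scale, phi)
  bg <- m_bg * config$background_level
  mean_a <- gain * (fp + kap * (1 - fp)) + bg
  mean_b <- gain * ((1 - fp) + kap * fp) + bg

  add_noise <- function(mu) {
    if (config$noise_cv == 0) return(pmax(mu, 0))
    sd <- config$noise_cv * m_noise * mu  # m_noise recycles down columns
    pmax(mu + matrix(stats::rnorm(length(mu)), nrow = n_arr) * sd, 0)
  }
  channels <- list(PM_A = add_noise(mean_a), PM_B = add_noise(mean_b))
  if (config$has_mismatch_probes) {
    mean_m <- matrix(bg, nrow = n_arr, ncol = P)
    channels$MM_A <- add_noise(mean_m)
    channels$MM_B <- add_noise(mean_m)
  }
  channels <- lapply(channels, function(m) {
    dimnames(m) <- list(arrays$array_id, NULL); m
  })
  structure(list(arrays = arrays, probes = probes, channels = channels,
                 has_mismatch = config$has_mismatch_probes),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Probe intensity matrix: %d hybridization(s) x %d probes (%d SNPs)\n",
              nrow(x$arrays), nrow(x$probes), length(unique(x$probes$snp_id))))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
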