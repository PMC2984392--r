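#' Partition a cohort into phenotype/sex/stratum/DNA-source matched pools
#'
#' Within every occupied (phenotype, sex, stratum, dna_source) cell the
#' individuals are randomly partitioned into pools of approximately the
#' target size: the number of pools is `max(1, round(n / target))` and
#' leftover individuals are spread so pool sizes within a cell differ by at
#' most one. Each member's DNA contribution weight is drawn from a gamma
#' distribution with the configured coefficient of variation around equal
#' shares and renormalized to sum to one (exactly equal when
#' `pipetting_cv = 0`). Pools sharing a cell form a biological replicate
#' group.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config The [snpmap_config()] used for the simulation.
#' @return An object of class `pool_design`: list with `pool_table`
#'   (data.frame: `pool_id`, `phenotype`, `sex`, `stratum`, `dna_source`,
#'   `n_members`, `replicate_group`) and `membership` (data.frame:
#'   `pool_id`, `member_id`, `weight`).
#' @examples
#' cfg <- snpmap_config(n_cases = 96, n_controls = 96, n_snps = 10, seed = 2)
#' design <- build_pools(simulate_cohort(cfg), cfg)
#' head(design$pool_table)
#' @export
build_pools <- function(cohort, config) {
  stopifnot(inherits(cohort, "snpmap_cohort"), inherits(config, "snpmap_config"))
  ind <- cohort$individuals
  cell <- interaction(ind$phenotype, ind$sex, ind$stratum, ind$dna_source,
                      drop = TRUE, sep = "/")
  if (any(tabulate(cell) == 0L))
    stop("pool design error: empty cell(s): ",
         paste(levels(cell)[tabulate(cell) == 0L], collapse = ", "), call. = FALSE)

  with_stage_seed(config$seed, "pools", {
    pool_rows <- list()
    member_rows <- list()
    pool_counter <- 0L
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      k <- max(1L, as.integer(round(n / config$target_pool_size)))
      # sizes differ by <= 1 within the cell
      sizes <- rep(n %/% k, k)
      if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      bounds <- cumsum(c(0L, sizes))
      parts <- strsplit(lv, "/", fixed = TRUE)[[1]]
      for (j in seq_len(k)) {
        pool_counter <- pool_counter + 1L
        pid <- sprintf("pool%03d", pool_counter)
        members <- ind$id[idx[(bounds[j] + 1):bounds[j + 1]]]
        w <- draw_weights(length(members), config$pipetting_cv)
        pool_rows[[pool_counter]] <- data.frame(
          pool_id = pid, phenotype = parts[1], sex = parts[2],
          stratum = parts[3], dna_source = parts[4],
          n_members = length(members),
          replicate_group = if (k >= 2L) lv else NA_character_,
          stringsAsFactors = FALSE)
        member_rows[[pool_counter]] <- data.frame(
          pool_id = pid, member_id = members, weight = w,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(pool_table = do.call(rbind, pool_rows),
                   membership = do.call(rbind, member_rows)),
              class = "pool_design")
  })
}

# Gamma-distributed contributions renormalized to sum to 1: positive at any
# CV, exactly 1/n when cv = 0.
draw_weights <- function(n, cv) {
  if (cv <= 0 || n == 1L) return(rep(1 / n, n))
  shape <- 1 / cv^2
  w <- stats::rgamma(n, shape = shape, rate = shape)
  w / sum(w)
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("Pool design: %d pools, %d individuals\n",
              nrow(x$pool_table), nrow(x$membership)))
  cat(sprintf("  sizes: mean %.2f (SD %.2f)\n",
              mean(x$pool_table$n_members), stats::sd(x$pool_table$n_members)))
  tab <- table(x$pool_table$phenotype, x$pool_table$dna_source)
  print(tab)
  invisible(x)
}

#' True weighted allele frequency of a pool
#'
#' The "real" pooled frequency that confirmatory individual genotyping
#' would measure: the contribution-weighted mean allele-A dosage over pool
#' members, `sum_i w_i * g_i / 2`.
#'
#' @param design A [build_pools()] design.
#' @param cohort The cohort the design was built from.
#' @param pool_id A pool identifier in the design.
#' @param snp_id A SNP identifier in the cohort (vector allowed).
#' @return Numeric frequency (or vector) in [0, 1].
#' @export
true_pool_frequency <- function(design, cohort, pool_id, snp_id) {
  stopifnot(inherits(design, "pool_design"), inherits(cohort, "snpmap_cohort"))
  m <- design$membership[design$membership$pool_id == pool_id, ]
  if (nrow(m) == 0L) stop("unknown pool: ", pool_id, call. = FALSE)
  if (!all(snp_id %in% colnames(cohort$genotypes)))
    stop("unknown SNP: ",
         paste(setdiff(snp_id, colnames(cohort$genotypes)), collapse = ", "),
         call. = FALSE)
  g <- cohort$genotypes[m$member_id, snp_id, drop = FALSE]
  unname(drop(crossprod(m$weight, g))) / 2
}

#' Matrix of true pooled allele frequencies
#'
#' @inheritParams true_pool_frequency
#' @return Numeric matrix pools x SNPs of weighted allele-A frequencies.
#' @export
pool_frequencies <- function(design, cohort) {
  stopifnot(inherits(design, "pool_design"), inherits(cohort, "snpmap_cohort"))
  ids <- design$pool_table$pool_id
  W <- matrix(0, nrow = length(ids), ncol = nrow(cohort$genotypes),
              dimnames = list(ids, rownames(cohort$genotypes)))
  W[cbind(match(design$membership$pool_id, ids),
          match(design$membership$member_id, rownames(cohort$genotypes)))] <-
    design$membership$weight
  (W %*% cohort$genotypes) / 2
}
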