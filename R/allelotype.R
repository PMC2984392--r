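#' Relative allele signal from perfect-match probes only
#'
#' On arrays without mismatch probes the per-probe score is the ratio of
#' allele signal intensities `A / (A + B)`; the SNP-level RAS is the mean of
#' the per-probe ratios (or the ratio of the summed intensities when
#' `summarization = "ratio_of_sums"`). Probes whose total signal is zero are
#' dropped; if every probe is dropped the score is `NA`.
#'
#' @param pm_a,pm_b Nonnegative per-probe intensities of the A and B
#'   channels.
#' @param summarization `"mean_ratio"` (default) or `"ratio_of_sums"`.
#' @return A fraction in [0, 1], or `NA` if no probe is scoreable.
#' @examples
#' ras_pm_only(300, 100)               # 0.75
#' ras_pm_only(c(300, 100), c(100, 300))  # mean(0.75, 0.25) = 0.5
#' @export
ras_pm_only <- function(pm_a, pm_b, summarization = c("mean_ratio", "ratio_of_sums")) {
  summarization <- match.arg(summarization)
  stopifnot(length(pm_a) == length(pm_b), length(pm_a) >= 1,
            all(pm_a >= 0), all(pm_b >= 0))
  tot <- pm_a + pm_b
  keep <- tot > 0
  if (!any(keep)) return(NA_real_)
  if (summarization == "mean_ratio") mean(pm_a[keep] / tot[keep])
  else sum(pm_a[keep]) / sum(tot[keep])
}

#' Relative allele signal with mismatch subtraction
#'
#' The scoring used on array generations that carry mismatch probes: each
#' channel's mismatch intensity (estimating nonspecific background) is
#' subtracted from its perfect-match intensity, negative differences are
#' clamped to zero, and the ratio `a / (a + b)` of the corrected signals is
#' summarized across probes as in [ras_pm_only()].
#'
#' @param pm_a,pm_b,mm_a,mm_b Nonnegative per-probe intensities.
#' @inheritParams ras_pm_only
#' @return A fraction in [0, 1], or `NA` if no probe is scoreable.
#' @examples
#' ras_mm_subtracted(300, 200, 100, 100)  # 200/300
#' @export
ras_mm_subtracted <- function(pm_a, pm_b, mm_a, mm_b,
                              summarization = c("mean_ratio", "ratio_of_sums")) {
  summarization <- match.arg(summarization)
  stopifnot(length(pm_a) == length(pm_b), length(mm_a) == length(pm_a),
            length(mm_b) == length(pm_a))
  ras_pm_only(pmax(pm_a - mm_a, 0), pmax(pm_b - mm_b, 0), summarization)
}

#' Allelotype every hybridization in an intensity matrix
#'
#' Applies the per-SNP RAS scorer to every array x SNP combination and
#' records how many probes survived the zero-signal guard. SNPs whose
#' probes are all unscoreable on an array are kept with `ras = NA` so
#' downstream stages can drop them explicitly.
#'
#' @param im An `intensity_matrix` from [simulate_intensities()] or
#'   [read_intensities()].
#' @param mode `"pm_only"` or `"mm_subtracted"`; the latter requires MM
#'   channels in the data.
#' @inheritParams ras_pm_only
#' @return A data.frame of class `ras_table` with columns `pool_id`,
#'   `array_id`, `snp_id`, `ras`, `probes_used`, and attributes `mode` and
#'   `summarization`.
#' @export
allelotype <- function(im, mode = c("pm_only", "mm_subtracted"),
                       summarization = c("mean_ratio", "ratio_of_sums")) {
  mode <- match.arg(mode)
  summarization <- match.arg(summarization)
  stopifnot(inherits(im, "intensity_matrix"))
  if (mode == "mm_subtracted" && is.null(im$channels$MM_A))
    stop("mode `mm_subtracted` requires MM channels, but this intensity ",
         "matrix has none (PM-only array design)", call. = FALSE)

  n_arr <- nrow(im$arrays)
  if (n_arr == 0L || nrow(im$probes) == 0L) {
    out <- data.frame(pool_id = character(), array_id = character(),
                      snp_id = character(), ras = numeric(),
                      probes_used = integer(), stringsAsFactors = FALSE)
    return(structure(out, mode = mode, summarization = summarization,
                     class = c("ras_table", "data.frame")))
  }

  if (mode == "pm_only") {
    a <- im$channels$PM_A
    b <- im$channels$PM_B
  } else {
    a <- pmax(im$channels$PM_A - im$channels$MM_A, 0)
    b <- pmax(im$channels$PM_B - im$channels$MM_B, 0)
  }
  tot <- a + b
  ok <- tot > 0
  snp_f <- factor(im$probes$snp_id, levels = unique(im$probes$snp_id))

  # per array x SNP: mean of per-probe ratios, or ratio of sums, over
  # scoreable probes (rowsum aggregates probes; arrays stay as columns)
  used <- rowsum(t(ok) + 0, snp_f)                      # snp x array counts
  if (summarization == "mean_ratio") {
    ratio <- ifelse(ok, a / tot, 0)
    num <- rowsum(t(ratio), snp_f)
    ras <- ifelse(used > 0, num / used, NA_real_)
  } else {
    asum <- rowsum(t(ifelse(ok, a, 0)), snp_f)
    tsum <- rowsum(t(ifelse(ok, tot, 0)), snp_f)
    ras <- ifelse(used > 0, asum / tsum, NA_real_)
  }

  snp_ids <- levels(snp_f)
  out <- data.frame(
    pool_id = rep(im$arrays$pool_id, each = length(snp_ids)),
    array_id = rep(im$arrays$array_id, each = length(snp_ids)),
    snp_id = rep(snp_ids, times = n_arr),
    ras = as.vector(ras),
    probes_used = as.integer(used),
    stringsAsFactors = FALSE)
  structure(out, mode = mode, summarization = summarization,
            class = c("ras_table", "data.frame"))
}

#' @export
print.ras_table <- function(x, ...) {
  cat(sprintf("RAS table: %d entries (%d hybridizations x %d SNPs), mode = %s\n",
              nrow(x), length(unique(x$array_id)), length(unique(x$snp_id)),
              attr(x, "mode")))
  if (anyNA(x$ras))
    cat(sprintf("  %d entries unscoreable (all probes dropped)\n", sum(is.na(x$ras))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

# Average technical replicate arrays into one RAS value per pool x SNP.
# Arrays are repeated measures of the same hybridized pool, so the pool --
# not the array -- is the unit of analysis downstream.
collapse_replicates <- function(ras) {
  stopifnot(inherits(ras, "ras_table"))
  keep <- !is.na(ras$ras)
  key <- interaction(ras$pool_id[keep], ras$snp_id[keep], drop = TRUE, sep = "\r")
  agg <- rowsum(ras$ras[keep], key) / tabulate(key)
  lab <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(pool_id = vapply(lab, `[`, "", 1),
             snp_id = vapply(lab, `[`, "", 2),
             ras = as.vector(agg), stringsAsFactors = FALSE)
}

# pools x SNPs matrix of replicate-collapsed RAS values (NA where missing)
ras_matrix <- function(ras) {
  cr <- collapse_replicates(ras)
  pools <- sort(unique(ras$pool_id))
  snps <- unique(ras$snp_id)
  m <- matrix(NA_real_, nrow = length(pools), ncol = length(snps),
              dimnames = list(pools, snps))
  m[cbind(match(cr$pool_id, pools), match(cr$snp_id, snps))] <- cr$ras
  m
}
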