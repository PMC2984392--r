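# Shared fixtures and independent brute-force oracles.

# Small, fast simulation configuration; override any field.
test_config <- function(...) {
  defaults <- list(n_cases = 96, n_controls = 96, n_snps = 30,
                   probes_per_snp = 4, pipetting_cv = 0,
                   n_technical_replicates = 1, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(snpmap_config, args)
}

# Build a cohort object by hand (fixture, not via the generator).
manual_cohort <- function(genotypes, phenotype = NULL, sex = "female",
                          stratum = "bmi1", dna_source = "blood") {
  n <- nrow(genotypes)
  if (is.null(phenotype)) phenotype <- rep("control", n)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("ind%05d", seq_len(n))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("snp%05d", seq_len(ncol(genotypes)))
  f <- colMeans(genotypes[phenotype == "control", , drop = FALSE]) / 2
  structure(list(
    individuals = data.frame(id = rownames(genotypes), phenotype = phenotype,
                             sex = rep_len(sex, n),
                             stratum = rep_len(stratum, n),
                             dna_source = rep_len(dna_source, n),
                             stringsAsFactors = FALSE),
    genotypes = genotypes,
    snp_table = data.frame(snp_id = colnames(genotypes), freq_a_control = f,
                           freq_a_case = f, true_maf_control = pmin(f, 1 - f),
                           is_effect = FALSE, stringsAsFactors = FALSE)),
    class = "snpmap_cohort")
}

# Build a pool design by hand from a list pool_id -> member ids (+ weights).
manual_design <- function(members, weights = NULL, phenotype = "control",
                          sex = "female", stratum = "bmi1",
                          dna_source = "blood", replicate_group = NA) {
  ids <- names(members)
  pt <- data.frame(pool_id = ids, phenotype = rep_len(phenotype, length(ids)),
                   sex = rep_len(sex, length(ids)),
                   stratum = rep_len(stratum, length(ids)),
                   dna_source = rep_len(dna_source, length(ids)),
                   n_members = lengths(members),
                   replicate_group = rep_len(replicate_group, length(ids)),
                   stringsAsFactors = FALSE)
  mm <- do.call(rbind, lapply(ids, function(p) {
    w <- if (is.null(weights[[p]])) rep(1 / length(members[[p]]),
                                        length(members[[p]])) else weights[[p]]
    data.frame(pool_id = p, member_id = members[[p]], weight = w,
               stringsAsFactors = FALSE)
  }))
  structure(list(pool_table = pt, membership = mm), class = "pool_design")
}

# Hand-built intensity matrix: each channel a hybridizations x probes matrix.
manual_im <- function(PM_A, PM_B, MM_A = NULL, MM_B = NULL, snp_id, probe_index,
                      pool_id = NULL, array_id = NULL) {
  PM_A <- rbind(PM_A); PM_B <- rbind(PM_B)
  n_arr <- nrow(PM_A)
  if (is.null(pool_id)) pool_id <- sprintf("pool%03d", seq_len(n_arr))
  if (is.null(array_id)) array_id <- paste0(pool_id, "_arr1")
  channels <- list(PM_A = PM_A, PM_B = PM_B)
  if (!is.null(MM_A)) {
    channels$MM_A <- rbind(MM_A)
    channels$MM_B <- rbind(MM_B)
  }
  channels <- lapply(channels, function(m) {
    dimnames(m) <- list(array_id, NULL); m
  })
  structure(list(
    arrays = data.frame(pool_id = pool_id, array_id = array_id,
                        dna_source = rep("blood", n_arr),
                        stringsAsFactors = FALSE),
    probes = data.frame(snp_id = snp_id, probe_index = probe_index,
                        stringsAsFactors = FALSE),
    channels = channels, has_mismatch = !is.null(MM_A)),
    class = "intensity_matrix")
}

# RAS table built directly from a pools x SNPs matrix of values.
manual_ras <- function(m, mode = "pm_only") {
  df <- data.frame(pool_id = rep(rownames(m), times = ncol(m)),
                   array_id = rep(paste0(rownames(m), "_arr1"), times = ncol(m)),
                   snp_id = rep(colnames(m), each = nrow(m)),
                   ras = as.vector(m), probes_used = 1L,
                   stringsAsFactors = FALSE)
  structure(df, mode = mode, summarization = "mean_ratio",
            class = c("ras_table", "data.frame"))
}

# --- independent textbook oracles (kept free of package internals) ---

oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# ratio-of-ratios summary via an explicit per-SNP loop
oracle_ror <- function(f_ctrl, f_case, ras_ctrl, ras_case, eps = 1e-6) {
  R <- c()
  for (i in seq_along(f_ctrl)) {
    if (f_case[i] > eps && ras_case[i] > eps && ras_ctrl[i] > eps &&
        f_ctrl[i] > eps)
      R <- c(R, (f_ctrl[i] / f_case[i]) / (ras_ctrl[i] / ras_case[i]))
  }
  mu <- mean(R)
  s <- sqrt(sum((R - mu)^2) / (length(R) - 1))
  list(mean = mu, sd = s,
       pct = 100 * sum(abs(R - mu) <= s) / length(R), n = length(R))
}

# RAS table of random pool values with case/control labels (scan fixture).
scan_fixture <- function(n_case = 5, n_control = 5, n_snps = 12, seed = 1,
                         shift = 0) {
  set.seed(seed)
  pools <- c(sprintf("case%02d", seq_len(n_case)),
             sprintf("ctrl%02d", seq_len(n_control)))
  m <- matrix(runif(length(pools) * n_snps, 0.2, 0.8), nrow = length(pools),
              dimnames = list(pools, sprintf("s%03d", seq_len(n_snps))))
  m[seq_len(n_case), 1] <- m[seq_len(n_case), 1] + shift
  design <- manual_design(stats::setNames(as.list(paste0("ind", seq_along(pools))),
                                          pools),
                          phenotype = rep(c("case", "control"),
                                          c(n_case, n_control)))
  list(ras = manual_ras(pmin(m, 1)), design = design)
}

# A scan with one genome-wide hit, a MAF-excluded SNP and null filler SNPs.
scan_fixture_for_followup <- function(seed = 4) {
  set.seed(seed)
  n <- 6
  m <- cbind(hit = c(rnorm(n, 0.8, 0.004), rnorm(n, 0.2, 0.004)),
             rare = runif(2 * n, 0.96, 0.99),
             matrix(runif(2 * n * 10, 0.3, 0.7), nrow = 2 * n,
                    dimnames = list(NULL, sprintf("null%02d", 1:10))))
  rownames(m) <- c(sprintf("ca%d", 1:n), sprintf("co%d", 1:n))
  design <- manual_design(stats::setNames(as.list(paste0("i", 1:(2 * n))),
                                          rownames(m)),
                          phenotype = rep(c("case", "control"), each = n))
  list(gwas = run_scan(manual_ras(pmin(pmax(m, 0), 1)), design),
       design = design)
}

# phenotype label per RAS row, via the design
ras_pool_pheno <- function(ras, design) {
  design$pool_table$phenotype[match(ras$pool_id, design$pool_table$pool_id)]
}
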