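#' Read and write genotype matrices
#'
#' The canonical interchange is a TSV of individuals x SNPs: first column
#' `id`, one column per SNP, allele-A dosages 0/1/2 with `.` for missing.
#' A minimal GT-only VCF (biallelic records, no genomic coordinates beyond
#' a running position) is supported for interoperability; non-biallelic
#' records are skipped with a warning.
#'
#' @param cohort A `snpmap_cohort` (or anything with a `genotypes` matrix).
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`; `read_genotypes` infers it from the
#'   file extension when not given.
#' @return `read_genotypes` returns an integer matrix individuals x SNPs
#'   with dimnames; writers return `path` invisibly.
#' @export
write_genotypes <- function(cohort, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  g <- if (inherits(cohort, "snpmap_cohort")) cohort$genotypes else cohort
  stopifnot(is.matrix(g))
  if (format == "tsv") {
    df <- data.frame(id = rownames(g), g, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(g))) {
      gt <- ifelse(is.na(g[, j]), "./.", gt_code[g[, j] + 1L])
      writeLines(paste(c("1", j, colnames(g)[j], "A", "B", ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, na.strings = ".",
                            colClasses = "character")
    if (names(df)[1] != "id")
      stop("malformed genotype TSV: first column must be `id` (line 1)",
           call. = FALSE)
    g <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(g) <- "integer")
    bad <- which(rowSums(is.na(g) & !is.na(as.matrix(df[, -1, drop = FALSE]))) > 0)
    if (length(bad))
      stop("malformed genotype TSV: non-numeric genotype token at line ",
           bad[1] + 1L, call. = FALSE)
    bad_val <- which(rowSums(!is.na(g) & (g < 0L | g > 2L)) > 0)
    if (length(bad_val))
      stop("malformed genotype TSV: genotype outside 0/1/2 at line ",
           bad_val[1] + 1L, call. = FALSE)
    rownames(g) <- df$id
    return(g)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", v@fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " non-biallelic VCF record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dose[] <- map[gt]
  t(dose)
}

#' Read and write pool designs
#'
#' Long TSV, one row per pool member: `pool_id`, `member_id`, `weight`,
#' `phenotype`, `sex`, `stratum`, `dna_source`, `replicate_group`.
#'
#' @param design A `pool_design`.
#' @param path File path.
#' @return `read_pool_design` returns a `pool_design`; the writer returns
#'   `path` invisibly.
#' @export
write_pool_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  pt <- design$pool_table
  df <- merge(design$membership, pt, by = "pool_id", sort = FALSE)
  df <- df[, c("pool_id", "member_id", "weight", "phenotype", "sex",
               "stratum", "dna_source", "replicate_group")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  need <- c("pool_id", "member_id", "weight", "phenotype", "sex", "stratum",
            "dna_source", "replicate_group")
  if (!all(need %in% names(df)))
    stop("malformed pool design TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  pt <- unique(df[, c("pool_id", "phenotype", "sex", "stratum", "dna_source",
                      "replicate_group")])
  pt$n_members <- as.integer(table(df$pool_id)[pt$pool_id])
  pt <- pt[, c("pool_id", "phenotype", "sex", "stratum", "dna_source",
               "n_members", "replicate_group")]
  rownames(pt) <- NULL
  structure(list(pool_table = pt,
                 membership = df[, c("pool_id", "member_id", "weight")]),
            class = "pool_design")
}

#' Read and write probe intensity matrices
#'
#' Long TSV, one row per hybridization x probe x channel: `pool_id`,
#' `array_id`, `snp_id`, `probe_index`, `channel` (PM_A/PM_B/MM_A/MM_B),
#' `intensity`.
#'
#' @param im An `intensity_matrix`.
#' @param path File path.
#' @return `read_intensities` returns an `intensity_matrix`; the writer
#'   returns `path` invisibly.
#' @export
write_intensities <- function(im, path) {
  stopifnot(inherits(im, "intensity_matrix"))
  P <- nrow(im$probes)
  n_arr <- nrow(im$arrays)
  blocks <- lapply(names(im$channels), function(ch) {
    data.frame(pool_id = rep(im$arrays$pool_id, each = P),
               array_id = rep(im$arrays$array_id, each = P),
               snp_id = rep(im$probes$snp_id, times = n_arr),
               probe_index = rep(im$probes$probe_index, times = n_arr),
               channel = ch,
               intensity = as.vector(t(im$channels[[ch]])),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pool_id", "array_id", "snp_id", "probe_index", "channel", "intensity")
  if (!all(need %in% names(df)))
    stop("malformed intensity TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (any(df$intensity < 0))
    stop("malformed intensity TSV: negative intensity at line ",
         which(df$intensity < 0)[1] + 1L, call. = FALSE)
  arrays <- unique(df[, c("pool_id", "array_id")])
  arrays$dna_source <- NA_character_
  rownames(arrays) <- NULL
  probes <- unique(df[, c("snp_id", "probe_index")])
  probes <- probes[order(match(probes$snp_id, unique(df$snp_id)),
                         probes$probe_index), ]
  rownames(probes) <- NULL
  pk <- paste(probes$snp_id, probes$probe_index, sep = "\r")
  channels <- lapply(split(df, df$channel), function(d) {
    m <- matrix(NA_real_, nrow = nrow(arrays), ncol = nrow(probes),
                dimnames = list(arrays$array_id, NULL))
    m[cbind(match(d$array_id, arrays$array_id),
            match(paste(d$snp_id, d$probe_index, sep = "\r"), pk))] <- d$intensity
    m
  })
  channels <- channels[intersect(c("PM_A", "PM_B", "MM_A", "MM_B"),
                                 names(channels))]
  structure(list(arrays = arrays, probes = probes, channels = channels,
                 has_mismatch = all(c("MM_A", "MM_B") %in% names(channels))),
            class = "intensity_matrix")
}

#' Read and write RAS tables
#'
#' TSV with columns `pool_id`, `array_id`, `snp_id`, `ras`, `probes_used`,
#' `mode`; missing RAS written as `.`.
#'
#' @param ras A `ras_table`.
#' @param path File path.
#' @return `read_ras` returns a `ras_table`; the writer returns `path`
#'   invisibly.
#' @export
write_ras <- function(ras, path) {
  stopifnot(inherits(ras, "ras_table"))
  df <- as.data.frame(ras)
  df$mode <- attr(ras, "mode")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_ras
#' @export
read_ras <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  need <- c("pool_id", "array_id", "snp_id", "ras", "probes_used", "mode")
  if (!all(need %in% names(df)))
    stop("malformed RAS TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  mode <- df$mode[1]
  df$mode <- NULL
  structure(df, mode = mode, summarization = NA_character_,
            class = c("ras_table", "data.frame"))
}

#' Write a GWAS result table
#'
#' TSV sorted by ascending p-value with one row per SNP.
#'
#' @param gwas A `pool_gwas`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  stopifnot(inherits(gwas, "pool_gwas"))
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
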