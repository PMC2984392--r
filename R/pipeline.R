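#' Validated end-to-end pipeline configuration
#'
#' Bundles the per-stage settings: simulation parameters (passed to
#' [snpmap_config()]), allelotyping mode and probe summarization, scan
#' thresholds, validation subset size and denominator guard, and I/O
#' format. Unknown keys in any section are rejected. The single top-level
#' seed drives every stage through named substreams, so re-running one
#' stage never changes another stage's draws.
#'
#' @param simulation Named list of [snpmap_config()] arguments (without
#'   `seed`).
#' @param allelotyping List with `mode` (`"pm_only"`/`"mm_subtracted"`) and
#'   `summarization` (`"mean_ratio"`/`"ratio_of_sums"`).
#' @param gwas List with `maf_threshold`, `alpha_gw`, `welch`.
#' @param validation List with `subset_size`, `epsilon`.
#' @param io List with `genotype_format` (`"tsv"` or `"vcf"`).
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(),
                            allelotyping = list(),
                            gwas = list(),
                            validation = list(),
                            io = list(),
                            seed = 1L) {
  take <- function(given, defaults, section) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop("unknown key(s) in `", section, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    utils::modifyList(defaults, given)
  }
  if ("seed" %in% names(simulation))
    stop("set the seed at the top level, not inside `simulation`", call. = FALSE)
  sim_cfg <- do.call(snpmap_config, c(simulation, list(seed = as.integer(seed))))
  al <- take(allelotyping,
             list(mode = "pm_only", summarization = "mean_ratio"), "allelotyping")
  al$mode <- match.arg(al$mode, c("pm_only", "mm_subtracted"))
  al$summarization <- match.arg(al$summarization, c("mean_ratio", "ratio_of_sums"))
  if (al$mode == "mm_subtracted" && !sim_cfg$has_mismatch_probes)
    stop("allelotyping mode `mm_subtracted` requires ",
         "`simulation$has_mismatch_probes = TRUE`", call. = FALSE)
  gw <- take(gwas, list(maf_threshold = 0.05, alpha_gw = 7.2e-8,
                        welch = FALSE), "gwas")
  va <- take(validation, list(subset_size = 110L, epsilon = 1e-6), "validation")
  io <- take(io, list(genotype_format = "tsv"), "io")
  io$genotype_format <- match.arg(io$genotype_format, c("tsv", "vcf"))
  structure(list(simulation = sim_cfg, allelotyping = al, gwas = gw,
                 validation = va, io = io, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("simulation", "allelotyping", "gwas", "validation", "io", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown top-level key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  do.call(pipeline_config, y)
}

#' Run the full pooled-allelotyping pipeline
#'
#' Executes simulate -> allelotype -> scan -> validate and writes every
#' intermediate as plain-text TSV plus a JSON manifest recording the seed,
#' package version, per-file row counts and SHA-256 hashes. Re-running with
#' the same configuration reproduces byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `design`, `intensities`, `ras`, `gwas`, `validation`), the `manifest`
#'   and the output `paths`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[poolmap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- config$simulation

  say("simulate: cohort of ", sim$n_cases, " cases + ", sim$n_controls,
      " controls, ", sim$n_snps, " SNPs")
  cohort <- stage("simulate", simulate_cohort(sim))
  design <- stage("simulate", build_pools(cohort, sim))
  im <- stage("simulate", simulate_intensities(design, cohort, sim))

  say("allelotype: mode ", config$allelotyping$mode)
  ras <- stage("allelotype",
               allelotype(im, config$allelotyping$mode,
                          config$allelotyping$summarization))

  say("gwas: ", attr(ras, "mode"), " RAS, MAF threshold ",
      config$gwas$maf_threshold)
  gwas <- stage("gwas", run_scan(ras, design,
                                 maf_threshold = config$gwas$maf_threshold,
                                 alpha_gw = config$gwas$alpha_gw,
                                 welch = config$gwas$welch))

  say("validate: subset of ", config$validation$subset_size, " SNPs")
  val <- stage("validate",
               validate_pools(ras, cohort, design, gwas,
                              subset_size = config$validation$subset_size,
                              epsilon = config$validation$epsilon,
                              seed = config$seed))

  gfmt <- config$io$genotype_format
  paths <- list(
    genotypes = file.path(outdir, paste0("genotypes.", gfmt)),
    individuals = file.path(outdir, "individuals.tsv"),
    pool_design = file.path(outdir, "pool_design.tsv"),
    intensities = file.path(outdir, "intensities.tsv"),
    ras = file.path(outdir, "ras.tsv"),
    gwas = file.path(outdir, "gwas.tsv"),
    validation = file.path(outdir, "validation.txt"))
  stage("write", {
    write_genotypes(cohort, paths$genotypes, gfmt)
    utils::write.table(cohort$individuals, paths$individuals, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    write_pool_design(design, paths$pool_design)
    write_intensities(im, paths$intensities)
    write_ras(ras, paths$ras)
    write_gwas(gwas, paths$gwas)
    write_validation_report(val, paths$validation)
  })

  manifest <- list(
    package = "poolmap",
    version = as.character(utils::packageVersion("poolmap")),
    seed = config$seed,
    stages = c("simulate", "allelotype", "gwas", "validate"),
    counts = list(
      individuals = nrow(cohort$individuals),
      snps = ncol(cohort$genotypes),
      pools = nrow(design$pool_table),
      hybridizations = nrow(im$arrays),
      probes = nrow(im$probes),
      ras_rows = nrow(ras),
      gwas_rows = nrow(gwas),
      genomewide_significant = sum(gwas$genomewide_significant)),
    files = lapply(paths, function(p)
      list(name = basename(p),
           sha256 = digest::digest(file = p, algo = "sha256"))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("done: ", outdir)
  invisible(list(cohort = cohort, design = design, intensities = im,
                 ras = ras, gwas = gwas, validation = val,
                 manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}

# Structured-text validation report: one TSV block per section.
write_validation_report <- function(val, path) {
  stopifnot(inherits(val, "snpmap_validation"))
  con <- file(path, "w")
  on.exit(close(con))
  block <- function(title, df) {
    writeLines(paste0("# ", title), con)
    if (is.null(df) || nrow(df) == 0) writeLines("(none)", con)
    else {
      tc <- textConnection("out", "w", local = TRUE)
      utils::write.table(df, tc, sep = "\t", quote = FALSE, row.names = FALSE,
                         na = ".")
      close(tc)
      writeLines(out, con)
    }
    writeLines("", con)
  }
  block("technical_replicate_correlations", val$technical)
  block("biological_replicate_mean_correlations", val$biological)
  block("ras_truth_correlation", val$truth_correlation)
  block("ratio_of_ratios", val$ratio_of_ratios)
  if (!is.null(val$followup_snps))
    block("followup_snps", data.frame(snp_id = val$followup_snps))
  invisible(path)
}
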