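#' Full simulation configuration
#'
#' Bundles the per-module configurations with one global seed from which
#' every module seed is derived deterministically (module sections left
#' `NULL` are skipped). Stage order is fixed: SNV, indel, CNV (which must
#' see the indel logs), allele realization, read generation.
#'
#' @param reference A `ref_genome` or a FASTA path.
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param snv,indel,cnv,reads Module configurations ([snv_config()],
#'   [indel_config()], [cnv_config()], [read_gen_config()]) or `NULL` to
#'   skip the stage.
#' @param profile A `quality_profile` or profile file path; required when
#'   `reads` is enabled.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reference, out_dir, seed = 1L, snv = snv_config(),
                       indel = NULL, cnv = NULL, reads = NULL, profile = NULL) {
  structure(list(reference = reference, out_dir = out_dir, seed = as.integer(seed),
                 snv = snv, indel = indel, cnv = cnv, reads = reads,
                 profile = profile),
            class = "sim_config")
}

#' Run the simulation pipeline
#'
#' Executes the enabled stages in order (SNV, indel, CNV, allele
#' realization, reads), writes all truth logs, allele FASTAs, FASTQ output
#' and a provenance manifest (`manifest.json`: configuration echo, seeds,
#' package version, output files). Each module receives a seed derived from
#' the global seed, so a fixed configuration reproduces identical outputs.
#'
#' @param config A [sim_config()].
#' @return Invisibly, a list with the truth sets (`snvs`, `indels`, `cnvs`),
#'   the realized `alleles`, and `files` (all written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$reference
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, paste0(...))
  files <- character(0)
  snvs <- indels <- cnvs <- NULL
  if (!is.null(config$snv)) {
    config$snv$seed <- derive_seed(config$seed, 101L)
    snvs <- simulate_snvs(genome, config$snv, log_path = path("snv_truth.tsv"))
    files <- c(files, path("snv_truth.tsv"))
  }
  if (!is.null(config$indel)) {
    config$indel$seed <- derive_seed(config$seed, 102L)
    indels <- simulate_indels(genome, config$indel, log_prefix = path("indel_truth"))
    files <- c(files, path("indel_truth_allele1.tsv"), path("indel_truth_allele2.tsv"))
  }
  if (!is.null(config$cnv)) {
    config$cnv$seed <- derive_seed(config$seed, 103L)
    cnvs <- simulate_cnvs(genome, config$cnv, indels = indels,
                          tab_path = path("cnv_truth.tsv"),
                          bed_path = path("cnv_truth.bed"))
    files <- c(files, path("cnv_truth.tsv"), path("cnv_truth.bed"))
  }
  if (!is.null(snvs) || !is.null(indels)) {
    write_truth_vcf(genome, snvs, indels, path("truth.vcf"))
    files <- c(files, path("truth.vcf"))
  }
  alleles <- c(apply_variants(genome, snvs, indels, cnvs, allele = 1L),
               apply_variants(genome, snvs, indels, cnvs, allele = 2L))
  for (k in 1:2) {
    sel <- alleles[vapply(alleles, function(a) a$allele == k, logical(1))]
    write_allele_fasta(sel, path("allele", k, ".fasta"))
    files <- c(files, path("allele", k, ".fasta"))
  }
  read_info <- NULL
  if (!is.null(config$reads)) {
    profile <- config$profile
    if (is.null(profile)) stop("read generation enabled but no quality profile given")
    if (is.character(profile)) profile <- read_quality_profile(profile)
    config$reads$seed <- derive_seed(config$seed, 104L)
    read_info <- generate_reads(alleles, profile, config$reads,
                                out_prefix = path("reads"))
    files <- c(files, read_info$paths)
  }
  manifest <- list(
    package = "diploidsim",
    version = as.character(utils::packageVersion("diploidsim")),
    seed = config$seed,
    stages = list(snv = !is.null(config$snv), indel = !is.null(config$indel),
                  cnv = !is.null(config$cnv), reads = !is.null(config$reads)),
    config = .echo_config(config),
    n_variants = list(snv = if (is.null(snvs)) 0L else nrow(snvs),
                      indel = if (is.null(indels)) 0L else nrow(indels),
                      cnv = if (is.null(cnvs)) 0L else nrow(cnvs)),
    files = files)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(snvs = snvs, indels = indels, cnvs = cnvs, alleles = alleles,
                 files = c(files, path("manifest.json")), reads = read_info))
}

# Serializable echo of the configuration (drops non-scalar objects).
.echo_config <- function(config) {
  lapply(config[c("snv", "indel", "cnv", "reads")], function(cfg) {
    if (is.null(cfg)) return(NULL)
    cfg <- unclass(cfg)
    cfg[!vapply(cfg, is.null, logical(1))]
  })
}
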