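#' SNV simulation parameters
#'
#' Defaults reflect human whole-genome expectations: an SNV rate of 0.001
#' (one SNV per kilobase), a transition/transversion ratio of 2.1, 20%
#' heterozygosity, and a 15-base minimum spacing between accepted SNVs. The
#' mean spacing of the placement walk, D_avg, is derived from the rate and
#' clamped to `[davg_lower, davg_upper]` (300-1000 bases by default, the
#' range supported by population-scale human resequencing).
#'
#' @param snv_rate Target SNV fraction of the genome, in (0, 1).
#' @param titv_ratio Transition/transversion ratio R > 0. R = 0.5 makes all
#'   three alternative bases equally likely (the random-substitution control).
#' @param het_fraction Probability a simulated SNV is heterozygous.
#' @param min_spacing Minimum distance (bases) between SNVs kept by the
#'   positional filter; pairs exactly `min_spacing` apart are kept.
#' @param davg_lower,davg_upper Clamp bounds for the mean spacing (bases).
#' @param spacing_sd Standard deviation of the Gaussian spacing walk; default
#'   `NULL` means D_avg / 4.
#' @param seed Optional integer seed set at the start of [simulate_snvs()].
#' @return A list of class `snv_config`.
#' @export
snv_config <- function(snv_rate = 0.001, titv_ratio = 2.1, het_fraction = 0.20,
                       min_spacing = 15L, davg_lower = 300L, davg_upper = 1000L,
                       spacing_sd = NULL, seed = NULL) {
  if (!is.numeric(snv_rate) || snv_rate <= 0 || snv_rate >= 1) {
    stop("snv_rate must lie strictly between 0 and 1")
  }
  stopifnot(titv_ratio > 0, het_fraction >= 0, het_fraction <= 1,
            min_spacing >= 1, davg_lower <= davg_upper)
  structure(list(snv_rate = snv_rate, titv_ratio = titv_ratio,
                 het_fraction = het_fraction, min_spacing = as.integer(min_spacing),
                 davg_lower = as.integer(davg_lower), davg_upper = as.integer(davg_upper),
                 spacing_sd = spacing_sd, seed = seed),
            class = "snv_config")
}

#' Mean SNV spacing from the requested rate
#'
#' `D_avg = clamp(round(1 / snv_rate), davg_lower, davg_upper)`. The clamp
#' means the realized SNV rate deviates from the requested rate outside the
#' supported range; this is reported, not corrected.
#'
#' @inheritParams snv_config
#' @return Integer mean spacing in bases.
#' @export
compute_davg <- function(snv_rate, davg_lower = 300L, davg_upper = 1000L) {
  if (!is.numeric(snv_rate) || snv_rate <= 0 || snv_rate >= 1) {
    stop("snv_rate must lie strictly between 0 and 1")
  }
  as.integer(min(max(round(1 / snv_rate), davg_lower), davg_upper))
}

#' Sample candidate SNV positions along one chromosome
#'
#' A random walk from the chromosome start: successive gaps are drawn from
#' Normal(D_avg, spacing_sd), rounded, and floored at `min_spacing`; the walk
#' stops past the chromosome end. With `spacing_sd = 0` the walk is the
#' deterministic grid D_avg, 2 D_avg, ...
#'
#' @param chrom_length Chromosome length in bases (>= 1).
#' @param cfg An `snv_config`.
#' @return Sorted integer positions in `[1, chrom_length]` (possibly empty).
#' @export
sample_snv_positions <- function(chrom_length, cfg = snv_config()) {
  stopifnot(chrom_length >= 1)
  davg <- compute_davg(cfg$snv_rate, cfg$davg_lower, cfg$davg_upper)
  sd <- cfg$spacing_sd %||% (davg / 4)
  gaps <- integer(0)
  total <- 0
  while (total <= chrom_length) {
    n_draw <- max(16L, ceiling((chrom_length - total) / davg * 1.25) + 8L)
    new <- pmax(round(stats::rnorm(n_draw, davg, sd)), cfg$min_spacing)
    gaps <- c(gaps, new)
    total <- total + sum(new)
  }
  pos <- cumsum(gaps)
  as.integer(pos[pos <= chrom_length])
}

#' Positional filter: enforce minimum SNV spacing
#'
#' Greedy left-to-right scan over sorted positions; a position closer than
#' `min_spacing` to the last kept position is dropped (the earlier of a
#' too-close pair is kept). Distances exactly equal to `min_spacing` pass.
#'
#' @param positions Sorted integer positions.
#' @param min_spacing Minimum allowed distance in bases.
#' @return Filtered positions.
#' @export
positional_filter <- function(positions, min_spacing = 15L) {
  n <- length(positions)
  if (n <= 1L) return(positions)
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- positions[1L]
  for (i in 2:n) {
    if (positions[i] - last >= min_spacing) {
      keep[i] <- TRUE
      last <- positions[i]
    }
  }
  positions[keep]
}

#' Drop SNV positions that fall in N-regions
#'
#' Positions inside any N interval are removed outright, never relocated.
#'
#' @param positions Integer 1-based positions.
#' @param n_regions data.frame of 0-based half-open `start`/`end` intervals.
#' @return Surviving positions.
#' @export
n_region_filter <- function(positions, n_regions) {
  positions[!positions_in_intervals(positions, n_regions)]
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSION1 <- c(A = "C", G = "C", C = "A", T = "A")
.TRANSVERSION2 <- c(A = "T", G = "T", C = "G", T = "G")

#' Choose alternate bases under a Ti/Tv constraint
#'
#' With probability `R / (R + 1)` the unique transition partner is emitted
#' (A<->G, C<->T); otherwise one of the two transversion partners, uniformly.
#' The expected count ratio transitions/transversions is therefore R, and
#' R = 0.5 reproduces uniform random substitution (Ti/Tv about 0.5).
#'
#' @param ref_base Character vector of reference bases in A/C/G/T.
#' @param titv_ratio R > 0.
#' @return data.frame with `alt` and `is_transition` columns.
#' @export
choose_alt_base <- function(ref_base, titv_ratio = 2.1) {
  if (length(ref_base) == 0L) {
    return(data.frame(alt = character(0), is_transition = logical(0)))
  }
  if (!all(ref_base %in% c("A", "C", "G", "T"))) {
    stop("ref_base must be A/C/G/T (N must be filtered upstream)")
  }
  n <- length(ref_base)
  is_ti <- stats::runif(n) < titv_ratio / (titv_ratio + 1)
  pick2 <- stats::runif(n) < 0.5
  alt <- ifelse(is_ti, .TRANSITION[ref_base],
                ifelse(pick2, .TRANSVERSION2[ref_base], .TRANSVERSION1[ref_base]))
  data.frame(alt = unname(alt), is_transition = is_ti)
}

#' Assign zygosity and allele to variants
#'
#' Heterozygous with probability `het_fraction`; heterozygous variants land
#' on allele 1 or 2 with a fair coin, homozygous variants on both.
#'
#' @param n Number of variants.
#' @param het_fraction Probability of heterozygosity.
#' @return data.frame with `zygosity` (`"het"`/`"hom"`) and `allele`
#'   (`"1"`, `"2"`, `"both"`).
#' @export
assign_zygosity <- function(n, het_fraction = 0.20) {
  if (n == 0L) return(data.frame(zygosity = character(0), allele = character(0)))
  het <- stats::runif(n) < het_fraction
  side <- ifelse(stats::runif(n) < 0.5, "1", "2")
  data.frame(zygosity = ifelse(het, "het", "hom"),
             allele = ifelse(het, side, "both"))
}

#' Simulate SNVs genome-wide
#'
#' Per chromosome: Gaussian spacing walk, positional filter, N-region filter,
#' Ti/Tv-constrained alternate-base choice, zygosity assignment. The SNV
#' count is emergent from the spacing walk (genome length / D_avg on
#' average), not pre-computed.
#'
#' @param genome A `ref_genome`.
#' @param cfg An [snv_config()].
#' @param log_path Optional path; when given, the truth set is written as a
#'   TSV with header `chrom pos ref alt zygosity allele ti_or_tv`.
#' @return data.frame of SNV truth records sorted by chromosome and position:
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `zygosity`, `allele`,
#'   `is_transition`.
#' @export
simulate_snvs <- function(genome, cfg = snv_config(), log_path = NULL) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- lapply(names(genome$chromosomes), function(chrom) {
    pos <- sample_snv_positions(genome$lengths[[chrom]], cfg)
    pos <- positional_filter(pos, cfg$min_spacing)
    pos <- n_region_filter(pos, genome$n_regions[[chrom]])
    if (length(pos) == 0L) return(NULL)
    raw <- charToRaw(genome$chromosomes[[chrom]])
    ref <- rawToChar(raw[pos], multiple = TRUE)
    ab <- choose_alt_base(ref, cfg$titv_ratio)
    zg <- assign_zygosity(length(pos), cfg$het_fraction)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = ab$alt,
               zygosity = zg$zygosity, allele = zg$allele,
               is_transition = ab$is_transition)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), zygosity = character(0),
                      allele = character(0), is_transition = logical(0))
  }
  rownames(out) <- NULL
  if (!is.null(log_path)) write_snv_log(out, log_path)
  out
}

#' Write an SNV truth log
#'
#' @param snvs SNV truth data.frame from [simulate_snvs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snv_log <- function(snvs, path) {
  df <- data.frame(chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref,
                   alt = snvs$alt, zygosity = snvs$zygosity, allele = snvs$allele,
                   ti_or_tv = ifelse(snvs$is_transition, "ti", "tv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SNV truth log written by [write_snv_log()]
#'
#' @param path TSV path.
#' @return SNV truth data.frame (same columns as [simulate_snvs()]).
#' @export
read_snv_log <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "character", "character",
                                         "character"))
  data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
             zygosity = df$zygosity, allele = df$allele,
             is_transition = df$ti_or_tv == "ti")
}
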