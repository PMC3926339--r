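#' CNV simulation parameters
#'
#' CNV size and location are generated dynamically: the user supplies only
#' the number of CNVs and the size range. Gains are realized as tandem
#' duplications (copy number 2..`max_copy_number` adjacent copies in the
#' allele sequence), losses as full-span deletions; both give depth-based CNV
#' callers the expected read-depth signal. Copy number is per allele: 1 means
#' unchanged, 0 loss, >= 2 tandem gain.
#'
#' @param n_cnvs Number of CNVs to place.
#' @param size_min,size_max CNV size bounds in bases (inclusive).
#' @param gain_fraction Probability a CNV is a gain (default 0.5).
#' @param max_copy_number Maximum copy number for gains (default 4).
#' @param allele_mode `"one"` (a random single allele), `"both"` or
#'   `"random"` (fair coin per allele, at least one affected).
#' @param retry_factor Rejection-sampling budget is `retry_factor * n_cnvs`
#'   candidate draws.
#' @param seed Optional integer seed set at the start of [simulate_cnvs()].
#' @return A list of class `cnv_config`.
#' @export
cnv_config <- function(n_cnvs, size_min, size_max, gain_fraction = 0.5,
                       max_copy_number = 4L, allele_mode = c("random", "one", "both"),
                       retry_factor = 1000L, seed = NULL) {
  allele_mode <- match.arg(allele_mode)
  stopifnot(n_cnvs >= 0, size_min >= 1, size_min <= size_max,
            gain_fraction >= 0, gain_fraction <= 1, max_copy_number >= 2)
  structure(list(n_cnvs = as.integer(n_cnvs), size_min = as.integer(size_min),
                 size_max = as.integer(size_max), gain_fraction = gain_fraction,
                 max_copy_number = as.integer(max_copy_number),
                 allele_mode = allele_mode, retry_factor = as.integer(retry_factor),
                 seed = seed),
            class = "cnv_config")
}

#' Draw CNV candidates
#'
#' Length-weighted chromosome choice; size uniform in
#' `[size_min, size_max]`; start uniform in `[1, chrom_len - size + 1]`;
#' gain/loss per `gain_fraction`; gains get a copy number uniform in
#' `[2, max_copy_number]`. Validity (overlaps, indel collisions) is checked
#' separately by [validate_cnv()].
#'
#' @param genome A `ref_genome`.
#' @param cfg A [cnv_config()].
#' @param n Number of candidates to draw.
#' @return data.frame with `chrom`, `start`, `end`, `size`,
#'   `cn_allele1`, `cn_allele2` (1-based inclusive spans).
#' @export
sample_cnv_candidate <- function(genome, cfg, n = 1L) {
  lens <- unname(genome$lengths)
  if (cfg$size_max > max(lens)) stop("size_max exceeds the longest chromosome")
  ok <- lens >= cfg$size_max  # only chromosomes that can host any size
  ci <- sample.int(length(lens), n, replace = TRUE, prob = lens * ok)
  size <- sample_range(cfg$size_min, cfg$size_max, n)
  start <- floor(stats::runif(n) * (lens[ci] - size + 1)) + 1L
  gain <- stats::runif(n) < cfg$gain_fraction
  cn_affected <- ifelse(gain,
                        sample_range(2L, cfg$max_copy_number, n), 0L)
  aff1 <- aff2 <- logical(n)
  if (cfg$allele_mode == "both") {
    aff1[] <- aff2[] <- TRUE
  } else if (cfg$allele_mode == "one") {
    aff1 <- stats::runif(n) < 0.5
    aff2 <- !aff1
  } else {  # random: fair coin per allele, redraw into "one" when neither hit
    aff1 <- stats::runif(n) < 0.5
    aff2 <- stats::runif(n) < 0.5
    none <- !aff1 & !aff2
    pick1 <- stats::runif(n) < 0.5
    aff1[none] <- pick1[none]
    aff2[none] <- !pick1[none]
  }
  data.frame(chrom = names(genome$chromosomes)[ci], start = start,
             end = start + size - 1L, size = size,
             cn_allele1 = ifelse(aff1, cn_affected, 1L),
             cn_allele2 = ifelse(aff2, cn_affected, 1L))
}

#' Validate a CNV candidate against boundaries, accepted CNVs and indels
#'
#' Rejects a candidate whose span exceeds the chromosome, overlaps any
#' already accepted CNV, or whose start or end falls inside a simulated
#' indel span on either allele (which also excludes indels straddling a
#' boundary). Indels fully contained in the span are allowed: tandem gain
#' copies carry them and losses erase them, so the realized alleles stay
#' well defined.
#'
#' @param candidate One-row CNV candidate.
#' @param chrom_length Reference length of the candidate's chromosome.
#' @param accepted Accepted CNV data.frame (may have zero rows).
#' @param indels_allele1,indels_allele2 Indel truth records applying to each
#'   allele (may be `NULL` or empty).
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
validate_cnv <- function(candidate, chrom_length, accepted,
                         indels_allele1 = NULL, indels_allele2 = NULL) {
  if (candidate$start < 1L || candidate$end > chrom_length) return(FALSE)
  if (!is.null(accepted) && nrow(accepted) > 0L) {
    same <- accepted[accepted$chrom == candidate$chrom, , drop = FALSE]
    if (nrow(same) > 0L &&
        any(candidate$start <= same$end & candidate$end >= same$start)) {
      return(FALSE)
    }
  }
  for (ind in list(indels_allele1, indels_allele2)) {
    if (is.null(ind) || nrow(ind) == 0L) next
    same <- ind[ind$chrom == candidate$chrom, , drop = FALSE]
    if (nrow(same) == 0L) next
    span_end <- same$pos + ifelse(same$kind == "deletion", same$length - 1L, 0L)
    for (b in c(candidate$start, candidate$end)) {
      if (any(same$pos <= b & b <= span_end)) return(FALSE)
    }
  }
  TRUE
}

#' Simulate allele-specific CNVs
#'
#' Rejection sampling: candidates are drawn with [sample_cnv_candidate()] and
#' accepted when [validate_cnv()] passes, until `n_cnvs` are logged or the
#' retry budget (`retry_factor * n_cnvs` draws) is exhausted, which raises a
#' capacity error stating how many were placed.
#'
#' @param genome A `ref_genome`.
#' @param cfg A [cnv_config()].
#' @param indels Indel truth data.frame from [simulate_indels()] (may be
#'   `NULL`); CNV boundaries avoid all indel spans on both alleles.
#' @param tab_path Optional path for the tabular truth file
#'   (`chrom start end size cn_allele1 cn_allele2`, 1-based inclusive).
#' @param bed_path Optional path for the BED-like file
#'   (`chrom start end name score`, 0-based half-open,
#'   score = max copy number).
#' @return data.frame of accepted CNV records sorted by chromosome and start.
#' @export
simulate_cnvs <- function(genome, cfg, indels = NULL,
                          tab_path = NULL, bed_path = NULL) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ind1 <- if (!is.null(indels) && nrow(indels) > 0L)
    indels[indels$allele %in% c("1", "both"), , drop = FALSE] else NULL
  ind2 <- if (!is.null(indels) && nrow(indels) > 0L)
    indels[indels$allele %in% c("2", "both"), , drop = FALSE] else NULL
  accepted <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                         size = integer(0), cn_allele1 = integer(0),
                         cn_allele2 = integer(0))
  budget <- cfg$retry_factor * max(cfg$n_cnvs, 1L)
  draws <- 0L
  while (nrow(accepted) < cfg$n_cnvs && draws < budget) {
    cand <- sample_cnv_candidate(genome, cfg, n = 1L)
    draws <- draws + 1L
    if (validate_cnv(cand, genome$lengths[[cand$chrom]], accepted, ind1, ind2)) {
      accepted <- rbind(accepted, cand)
    }
  }
  if (nrow(accepted) < cfg$n_cnvs) {
    stop("CNV capacity error: placed ", nrow(accepted), " of ", cfg$n_cnvs,
         " CNVs within the retry budget (", budget, " draws)")
  }
  ci <- match(accepted$chrom, names(genome$chromosomes))
  accepted <- accepted[order(ci, accepted$start), , drop = FALSE]
  rownames(accepted) <- NULL
  if (!is.null(tab_path)) {
    utils::write.table(accepted, tab_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = accepted$chrom, start = accepted$start - 1L,
                      end = accepted$end,
                      name = paste0("cnv_", seq_len(nrow(accepted)),
                                    recycle0 = TRUE),
                      score = pmax(accepted$cn_allele1, accepted$cn_allele2))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  accepted
}
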