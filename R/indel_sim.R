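#' Indel simulation parameters
#'
#' Category fractions follow the literature-based human mix: 30% single-base
#' indels, 20% repeat expansions, 49% 2-20 bp indels and 1% long (21-100 bp)
#' indels. Insertions:deletions and heterozygous:homozygous are both 1:1.
#' Because repeat expansions are realized as insertions, the insertion
#' probability of the remaining categories is compensated so the OVERALL
#' insertion:deletion ratio matches `ins_del_ratio` (0.375 per non-repeat
#' candidate under the defaults).
#'
#' @param n_indels Requested final indel count; alternatively give
#'   `indel_rate` (per base) and the count is `round(rate * genome length)`.
#' @param indel_rate Optional per-base rate used when `n_indels` is `NULL`.
#' @param overgen_fraction Over-generation fraction compensating losses at
#'   the duplicate-removal step (default 0.05, i.e. +5%).
#' @param category_fracs Named fractions over
#'   `single`, `repeat_expansion`, `mid`, `long`; must sum to 1.
#' @param ins_del_ratio Target overall insertion/deletion count ratio.
#' @param het_hom_ratio Target heterozygous/homozygous count ratio (may be
#'   `Inf` for all-het or 0 for all-hom).
#' @param motif_len_range Motif length bounds (bases) for repeat expansions.
#' @param copies_range Copy-count bounds for repeat expansions.
#' @param max_redraws Redraw rounds allowed when positions collide with
#'   N-regions before giving up.
#' @param seed Optional integer seed set at the start of [simulate_indels()].
#' @return A list of class `indel_config`.
#' @export
indel_config <- function(n_indels = NULL, indel_rate = NULL,
                         overgen_fraction = 0.05,
                         category_fracs = c(single = 0.30, repeat_expansion = 0.20,
                                            mid = 0.49, long = 0.01),
                         ins_del_ratio = 1, het_hom_ratio = 1,
                         motif_len_range = c(1L, 5L), copies_range = c(2L, 4L),
                         max_redraws = 100L, seed = NULL) {
  stopifnot(abs(sum(category_fracs) - 1) < 1e-9,
            all(names(category_fracs) == c("single", "repeat_expansion", "mid", "long")),
            overgen_fraction >= 0, ins_del_ratio >= 0, het_hom_ratio >= 0)
  structure(list(n_indels = n_indels, indel_rate = indel_rate,
                 overgen_fraction = overgen_fraction, category_fracs = category_fracs,
                 ins_del_ratio = ins_del_ratio, het_hom_ratio = het_hom_ratio,
                 motif_len_range = as.integer(motif_len_range),
                 copies_range = as.integer(copies_range),
                 max_redraws = as.integer(max_redraws), seed = seed),
            class = "indel_config")
}

#' Initial candidate count with over-generation
#'
#' `ceiling(n_requested * (1 + overgen_fraction))`: the extra 5% absorbs the
#' 2-5% of candidates typically lost to duplicate/overlap removal.
#'
#' @param n_requested Requested final count.
#' @param overgen_fraction Over-generation fraction.
#' @return Integer initial count.
#' @export
overgenerate_count <- function(n_requested, overgen_fraction = 0.05) {
  stopifnot(n_requested >= 0)
  as.integer(ceiling(n_requested * (1 + overgen_fraction)))
}

#' Apportion candidates across indel categories
#'
#' Largest-remainder apportionment (deterministic, ties by category order) so
#' counts sum exactly to `n` and each is within 1 of `n * fraction`.
#'
#' @param n Total count.
#' @param category_fracs Named category fractions.
#' @return Named integer vector over the four categories.
#' @export
allocate_categories <- function(n, category_fracs = c(single = 0.30,
                                                      repeat_expansion = 0.20,
                                                      mid = 0.49, long = 0.01)) {
  stats::setNames(largest_remainder(n, category_fracs), names(category_fracs))
}

# Insertion probability for non-repeat candidates such that the overall
# ins:del ratio hits the target despite repeat expansions being insertions.
.p_ins_other <- function(cfg) {
  f_ins <- if (is.infinite(cfg$ins_del_ratio)) 1 else cfg$ins_del_ratio / (cfg$ins_del_ratio + 1)
  f_rep <- cfg$category_fracs[["repeat_expansion"]]
  p <- (f_ins - f_rep) / (1 - f_rep)
  if (p < 0 || p > 1) {
    warning("ins_del_ratio unreachable with this repeat-expansion fraction; clamping")
    p <- min(max(p, 0), 1)
  }
  p
}

#' Sample one indel candidate
#'
#' Chromosome is drawn length-weighted; position uniform, redrawn while it
#' (or, for deletions, its span) touches an N-region. Lengths: `single` is 1,
#' `mid` uniform 2-20, `long` uniform 21-100; `repeat_expansion` picks a
#' motif length uniform in `motif_len_range` from the sequence immediately
#' left of the anchor and inserts 2-4 tandem copies of that motif. Deletion
#' sequences are read from the reference (bases `pos .. pos+len-1`);
#' insertions anchor after `pos`.
#'
#' @param genome A `ref_genome`.
#' @param category One of `"single"`, `"repeat_expansion"`, `"mid"`, `"long"`.
#' @param cfg An [indel_config()].
#' @return One-row indel candidate data.frame.
#' @export
sample_indel <- function(genome, category, cfg = indel_config()) {
  .sample_indel_candidates(genome, stats::setNames(as.integer(names(cfg$category_fracs) == category),
                                                   names(cfg$category_fracs)), cfg)
}

.sample_indel_candidates <- function(genome, counts, cfg) {
  n <- sum(counts)
  empty <- data.frame(chrom = character(0), pos = integer(0), kind = character(0),
                      length = integer(0), seq = character(0), category = character(0))
  if (n == 0L) return(empty)
  category <- rep(names(counts), counts)
  p_ins <- .p_ins_other(cfg)
  is_rep <- category == "repeat_expansion"
  kind <- ifelse(is_rep, "insertion",
                 ifelse(stats::runif(n) < p_ins, "insertion", "deletion"))
  len <- integer(n)
  len[category == "single"] <- 1L
  len[category == "mid"] <- sample_range(2L, 20L, sum(category == "mid"))
  len[category == "long"] <- sample_range(21L, 100L, sum(category == "long"))
  motif_len <- copies <- integer(n)
  if (any(is_rep)) {
    motif_len[is_rep] <- sample_range(cfg$motif_len_range[1], cfg$motif_len_range[2],
                                sum(is_rep))
    copies[is_rep] <- sample_range(cfg$copies_range[1], cfg$copies_range[2],
                             sum(is_rep))
    len[is_rep] <- motif_len[is_rep] * copies[is_rep]
  }
  chrom_names <- names(genome$chromosomes)
  lens <- unname(genome$lengths)
  ci <- integer(n)
  pos <- integer(n)
  todo <- rep(TRUE, n)
  for (round in seq_len(cfg$max_redraws)) {
    k <- sum(todo)
    if (k == 0L) break
    ci[todo] <- sample.int(length(lens), k, replace = TRUE, prob = lens)
    pos[todo] <- floor(stats::runif(k) * lens[ci[todo]]) + 1L
    bad <- logical(n)
    for (c_idx in unique(ci[todo])) {
      sel <- todo & ci == c_idx
      nreg <- genome$n_regions[[c_idx]]
      clen <- lens[c_idx]
      del <- sel & kind == "deletion"
      insv <- sel & kind == "insertion"
      # deletion: left VCF anchor must exist, span fits, span clear of N
      bad[del] <- pos[del] < 2L | (pos[del] + len[del] - 1L) > clen |
        spans_overlap_intervals(pos[del], pos[del] + len[del] - 1L, nreg)
      # insertion: anchor base not N; repeat expansions also need a clean
      # left context of motif_len bases
      bad[insv] <- positions_in_intervals(pos[insv], nreg)
      repi <- insv & is_rep
      if (any(repi)) {
        bad[repi] <- bad[repi] | pos[repi] < motif_len[repi] |
          spans_overlap_intervals(pmax(pos[repi] - motif_len[repi] + 1L, 1L),
                                  pos[repi], nreg)
      }
    }
    todo <- bad
  }
  if (any(todo)) {
    stop(sum(todo), " indel candidate(s) could not be placed outside N-regions ",
         "after ", cfg$max_redraws, " redraw rounds")
  }
  seqs <- character(n)
  other_ins <- kind == "insertion" & !is_rep
  seqs[other_ins] <- random_dna(len[other_ins])
  for (c_idx in unique(ci)) {
    s <- genome$chromosomes[[c_idx]]
    del <- ci == c_idx & kind == "deletion"
    if (any(del)) seqs[del] <- substring(s, pos[del], pos[del] + len[del] - 1L)
    repi <- ci == c_idx & is_rep
    if (any(repi)) {
      motifs <- substring(s, pos[repi] - motif_len[repi] + 1L, pos[repi])
      seqs[repi] <- strrep(motifs, copies[repi])
    }
  }
  data.frame(chrom = chrom_names[ci], pos = pos, kind = kind, length = len,
             seq = seqs, category = category)
}

#' Coordinate-sort candidates, drop duplicates and overlaps, trim to target
#'
#' Candidates are sorted by (chromosome, position); all but the first record
#' at a duplicated position are dropped, as is any record whose span overlaps
#' a previously kept record (insertions occupy their anchor base, deletions
#' their full span). The survivors are truncated to `n_requested` from the
#' sorted tail, discarding the over-generation excess deterministically.
#'
#' @param candidates Candidate data.frame from the sampling step.
#' @param n_requested Final count to keep (`Inf` keeps all survivors).
#' @param chrom_order Chromosome ordering (defaults to order of appearance).
#' @return Deduplicated, sorted data.frame.
#' @export
dedup_sort <- function(candidates, n_requested = Inf,
                       chrom_order = unique(candidates$chrom)) {
  if (nrow(candidates) == 0L) return(candidates)
  ci <- match(candidates$chrom, chrom_order)
  ord <- order(ci, candidates$pos)
  x <- candidates[ord, , drop = FALSE]
  ci <- ci[ord]
  span_end <- x$pos + ifelse(x$kind == "deletion", x$length - 1L, 0L)
  n <- nrow(x)
  keep <- logical(n)
  last_c <- -1L
  last_end <- -1L
  for (i in seq_len(n)) {
    if (ci[i] != last_c || x$pos[i] > last_end) {
      keep[i] <- TRUE
      last_c <- ci[i]
      last_end <- span_end[i]
    }
  }
  x <- x[keep, , drop = FALSE]
  if (is.finite(n_requested) && nrow(x) > n_requested) {
    x <- x[seq_len(n_requested), , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Assign zygosity and allele to indel records
#'
#' Heterozygous with probability `r / (r + 1)` where `r = het_hom_ratio`
#' (1:1 default, i.e. 0.5); heterozygous records land on allele 1 or 2 with a
#' fair coin, homozygous records on both alleles.
#'
#' @param records Indel data.frame.
#' @param het_hom_ratio Heterozygous/homozygous target ratio.
#' @return `records` with `zygosity` and `allele` columns added.
#' @export
assign_indel_zygosity <- function(records, het_hom_ratio = 1) {
  p_het <- if (is.infinite(het_hom_ratio)) 1 else het_hom_ratio / (het_hom_ratio + 1)
  zg <- assign_zygosity(nrow(records), p_het)
  records$zygosity <- zg$zygosity
  records$allele <- zg$allele
  records
}

#' Simulate indels genome-wide
#'
#' End to end: over-generate candidates (+5%), apportion across the four
#' size/mechanism categories, place them outside N-regions, coordinate-sort
#' with duplicate and overlap removal, trim to the requested count, and
#' assign zygosity. Two allele-specific truth logs are written when
#' `log_prefix` is given (`<prefix>_allele1.tsv`, `<prefix>_allele2.tsv`),
#' reflecting the bi-allelic nature of the simulated genome: homozygous
#' records appear in both files.
#'
#' @param genome A `ref_genome`.
#' @param cfg An [indel_config()]; `n_indels` or `indel_rate` must be set.
#' @param log_prefix Optional path prefix for the two truth logs.
#' @return data.frame of indel truth records: `chrom`, `pos` (1-based
#'   anchor; first deleted base for deletions, base before the insertion for
#'   insertions), `kind`, `length`, `seq`, `category`, `zygosity`, `allele`.
#' @export
simulate_indels <- function(genome, cfg = indel_config(), log_prefix = NULL) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_req <- cfg$n_indels %||%
    if (!is.null(cfg$indel_rate)) round(cfg$indel_rate * sum(genome$lengths)) else
      stop("indel_config needs n_indels or indel_rate")
  n_init <- overgenerate_count(n_req, cfg$overgen_fraction)
  counts <- allocate_categories(n_init, cfg$category_fracs)
  cand <- .sample_indel_candidates(genome, counts, cfg)
  kept <- dedup_sort(cand, n_req, chrom_order = names(genome$chromosomes))
  if (nrow(kept) < n_req) {
    warning("only ", nrow(kept), " of ", n_req, " requested indels survived dedup")
  }
  out <- assign_indel_zygosity(kept, cfg$het_hom_ratio)
  if (!is.null(log_prefix)) write_indel_logs(out, log_prefix)
  out
}

#' Write the two allele-specific indel truth logs
#'
#' @param indels Indel truth data.frame.
#' @param prefix Path prefix; writes `<prefix>_allele1.tsv` and
#'   `<prefix>_allele2.tsv`.
#' @return The two paths, invisibly.
#' @export
write_indel_logs <- function(indels, prefix) {
  paths <- paste0(prefix, "_allele", 1:2, ".tsv")
  for (k in 1:2) {
    sel <- indels$allele %in% c(as.character(k), "both")
    utils::write.table(
      indels[sel, c("chrom", "pos", "kind", "length", "seq", "category", "zygosity")],
      paths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Summarize indels by the short/medium/large size tripartition
#'
#' Reports the 1-10 / 11-20 / 21-100 bp view alongside the category mix.
#'
#' @param indels Indel truth data.frame.
#' @return Named table of counts over `short`, `medium`, `large`.
#' @export
indel_size_summary <- function(indels) {
  cls <- cut(indels$length, breaks = c(0, 10, 20, 100),
             labels = c("short", "medium", "large"))
  table(cls)
}
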