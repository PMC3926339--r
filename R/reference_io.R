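#' Construct a reference genome object
#'
#' Normalizes chromosome sequences (uppercase; any character other than
#' A/C/G/T, including IUPAC ambiguity codes, becomes N) and records the
#' N-regions -- maximal runs of non-ACGT bases -- as sorted disjoint 0-based
#' half-open intervals. Variant placement later excludes these regions.
#'
#' @param sequences Named character vector or named list of chromosome
#'   sequences. Names must be unique and non-empty.
#' @return An object of class `ref_genome` with elements `chromosomes`
#'   (named uppercase character vector), `n_regions` (named list of
#'   data.frames with `start`/`end` columns) and `lengths`.
#' @export
ref_genome <- function(sequences) {
  sequences <- unlist(sequences)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("every chromosome must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  empty <- !nzchar(sequences)
  if (any(empty)) stop("empty sequence for record(s): ", paste(nm[empty], collapse = ", "))
  seqs <- gsub("[^ACGT]", "N", toupper(sequences), perl = TRUE)
  names(seqs) <- nm
  structure(
    list(
      chromosomes = seqs,
      n_regions = lapply(seqs, find_n_regions),
      lengths = stats::setNames(nchar(seqs), nm)
    ),
    class = "ref_genome"
  )
}

#' @exportS3Method base::print
print.ref_genome <- function(x, ...) {
  nbases <- vapply(x$n_regions, function(r) sum(r$end - r$start), numeric(1))
  cat("ref_genome:", length(x$chromosomes), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bases",
      sprintf("(%.2f%% N)\n", 100 * sum(nbases) / sum(x$lengths)))
  invisible(x)
}

#' Locate N-regions in a normalized sequence
#'
#' @param sequence A normalized (uppercase ACGTN) nucleotide string.
#' @return data.frame with 0-based half-open `start`/`end` columns, one row
#'   per maximal run of non-ACGT characters; zero rows if none.
#' @export
find_n_regions <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr("[^ACGT]+", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + attr(m, "match.length"))
}

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] (plain or gzipped FASTA, wrapped
#' sequence lines) and applies [ref_genome()] normalization. Header
#' descriptions after the first whitespace are dropped.
#'
#' @param path Path to a FASTA file.
#' @return A `ref_genome` object; chromosome order is file order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ref_genome(stats::setNames(as.character(seqs), names(seqs)))
}

#' Apply variants to a reference genome, producing one allele
#'
#' Realizes the mutated sequence of a single allele: SNVs are substituted,
#' insertions are added after their anchor base, deletion spans are removed,
#' CNV losses (copy number 0) are removed and CNV gains (copy number k >= 2)
#' become k tandem copies of the span. A variant applies to the requested
#' allele when its `allele` field is `"both"` (homozygous) or matches
#' `allele`; CNVs apply when the per-allele copy number differs from 1.
#' Indels fully contained in a CNV span are carried by every tandem copy of
#' a gain and erased by a loss; an indel crossing a CNV boundary is an
#' error (the CNV simulator never produces one).
#'
#' @param genome A `ref_genome`.
#' @param snvs,indels,cnvs Truth data.frames as produced by
#'   [simulate_snvs()], [simulate_indels()] and [simulate_cnvs()]; any may be
#'   `NULL`.
#' @param allele Which allele to realize, 1 or 2.
#' @return Named list (one entry per chromosome) of `allele_seq` objects:
#'   `chrom`, `allele`, `sequence`, and `coord_map`, a piecewise
#'   reference-to-allele coordinate map (see [map_ref_to_allele()]).
#' @export
apply_variants <- function(genome, snvs = NULL, indels = NULL, cnvs = NULL, allele = 1L) {
  stopifnot(inherits(genome, "ref_genome"), allele %in% c(1L, 2L))
  out <- lapply(names(genome$chromosomes), function(chrom) {
    .apply_variants_chrom(
      chrom, genome$chromosomes[[chrom]],
      .select_allele(snvs, allele, chrom),
      .select_allele(indels, allele, chrom),
      .select_cnv_allele(cnvs, allele, chrom),
      allele
    )
  })
  stats::setNames(out, names(genome$chromosomes))
}

.select_allele <- function(df, allele, chrom) {
  if (is.null(df) || nrow(df) == 0L) return(df[0, ])
  df[df$chrom == chrom & (df$allele == "both" | df$allele == as.character(allele)), , drop = FALSE]
}

.select_cnv_allele <- function(cnvs, allele, chrom) {
  if (is.null(cnvs) || nrow(cnvs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), cn = integer(0)))
  }
  cn <- if (allele == 1L) cnvs$cn_allele1 else cnvs$cn_allele2
  sel <- cnvs$chrom == chrom & cn != 1L
  data.frame(start = cnvs$start[sel], end = cnvs$end[sel], cn = cn[sel])
}

.apply_variants_chrom <- function(chrom, seq, snvs, indels, cnvs, allele) {
  len <- nchar(seq)
  # SNVs: in-place byte substitution after checking the logged reference base.
  if (!is.null(snvs) && nrow(snvs) > 0L) {
    if (any(snvs$pos < 1L | snvs$pos > len)) stop("SNV position outside ", chrom)
    raw <- charToRaw(seq)
    obs <- rawToChar(raw[snvs$pos], multiple = TRUE)
    if (any(obs != snvs$ref)) stop("SNV ref allele mismatch on ", chrom)
    raw[snvs$pos] <- charToRaw(paste0(snvs$alt, collapse = ""))
    seq <- rawToChar(raw)
  }
  # Indel edits: each op owns a reference span, empty for insertions (an
  # insertion after pos is encoded [pos+1, pos]).
  if (!is.null(indels) && nrow(indels) > 0L) {
    is_ins <- indels$kind == "insertion"
    iop <- data.frame(
      ref_start = ifelse(is_ins, indels$pos + 1L, indels$pos),
      ref_end = ifelse(is_ins, indels$pos, indels$pos + indels$length - 1L),
      piece = ifelse(is_ins, indels$seq, ""),
      insertion = is_ins)
    iop <- iop[order(iop$ref_start, iop$ref_end), , drop = FALSE]
  } else {
    iop <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      piece = character(0), insertion = logical(0))
  }
  if (nrow(cnvs) > 0L) cnvs <- cnvs[order(cnvs$start), , drop = FALSE]
  if (any(iop$ref_start < 1L | iop$ref_end > len) ||
      (nrow(cnvs) > 0L && any(cnvs$start < 1L | cnvs$end > len))) {
    stop("variant coordinates outside ", chrom)
  }
  if (nrow(cnvs) > 1L && any(cnvs$start[-1L] <= cnvs$end[-nrow(cnvs)])) {
    stop("overlapping CNV spans on one allele of ", chrom, " (upstream bug)")
  }
  # Assign each indel to the CNV span containing it (if any). Indels fully
  # inside a CNV are carried by every tandem copy of a gain and vanish with
  # a loss; an indel crossing a CNV boundary is an upstream bug.
  container <- rep(NA_integer_, nrow(iop))
  if (nrow(cnvs) > 0L && nrow(iop) > 0L) {
    lo <- ifelse(iop$insertion, iop$ref_end, iop$ref_start)  # anchor base for ins
    j <- findInterval(lo, cnvs$start)
    jj <- pmax(j, 1L)
    touches <- j >= 1L & lo <= cnvs$end[jj]
    inside <- touches & ifelse(iop$insertion,
                               lo < cnvs$end[jj],            # pos == end: after span
                               iop$ref_end <= cnvs$end[jj])
    straddle <- (touches & !inside & !iop$insertion) |
      (!touches & j < nrow(cnvs) & cnvs$start[pmin(j + 1L, nrow(cnvs))] <= iop$ref_end)
    if (any(straddle)) {
      stop("indel span crosses a CNV boundary on ", chrom, " (upstream bug)")
    }
    container[inside] <- jj[inside]
  }
  # Merge top-level ops: uncontained indels plus CNVs, sorted, disjoint.
  free <- which(is.na(container))
  top <- rbind(
    data.frame(ref_start = iop$ref_start[free],
               ref_end = iop$ref_end[free],
               kind = ifelse(iop$insertion[free], "insertion", "deletion"),
               piece = iop$piece[free],
               cn = rep(NA_integer_, length(free)),
               cnv_idx = rep(NA_integer_, length(free))),
    if (nrow(cnvs) > 0L) data.frame(ref_start = cnvs$start, ref_end = cnvs$end,
                                    kind = ifelse(cnvs$cn == 0L, "cnv_loss", "cnv_gain"),
                                    piece = "", cn = cnvs$cn,
                                    cnv_idx = seq_len(nrow(cnvs))))
  top <- top[order(top$ref_start, top$ref_end), , drop = FALSE]
  if (nrow(top) > 1L && any(top$ref_start[-1L] <= top$ref_end[-nrow(top)])) {
    stop("overlapping variant spans on one allele of ", chrom, " (upstream bug)")
  }
  # Assemble pieces and the piecewise coordinate map in one pass.
  n_ops <- nrow(top)
  cap <- 2L * (n_ops + nrow(iop)) + nrow(cnvs) + 4L
  pieces <- character(cap)
  seg_start <- seg_end <- seg_off <- seg_left <- integer(cap)
  seg_del <- logical(cap)
  np <- 0L  # pieces used
  ns <- 0L  # map segments used
  add_seg <- function(rs, re, off, deleted, left) {
    ns <<- ns + 1L
    seg_start[ns] <<- rs; seg_end[ns] <<- re; seg_off[ns] <<- off
    seg_del[ns] <<- deleted; seg_left[ns] <<- left
  }
  # Realize one copy of [from, to] applying the contained indel ops; emits
  # map segments for the first copy (offset0 = allele offset at `from`).
  assemble_span <- function(from, to, sub, offset0, map_first_copy) {
    sub_pieces <- character(2L * nrow(sub) + 1L)
    k <- 0L
    prev <- from - 1L
    off <- offset0
    for (s in seq_len(nrow(sub))) {
      rs <- sub$ref_start[s]; re <- sub$ref_end[s]
      if (rs > prev + 1L) {
        k <- k + 1L
        sub_pieces[k] <- substring(seq, prev + 1L, rs - 1L)
        if (map_first_copy) add_seg(prev + 1L, rs - 1L, off, FALSE, NA_integer_)
      }
      if (sub$insertion[s]) {
        k <- k + 1L
        sub_pieces[k] <- sub$piece[s]
        off <- off + nchar(sub$piece[s])
      } else {
        if (map_first_copy) add_seg(rs, re, 0L, TRUE, max(rs - 1L + off, 0L))
        off <- off - (re - rs + 1L)
      }
      prev <- re
    }
    if (prev < to) {
      k <- k + 1L
      sub_pieces[k] <- substring(seq, prev + 1L, to)
      if (map_first_copy) add_seg(prev + 1L, to, off, FALSE, NA_integer_)
    }
    paste0(sub_pieces[seq_len(k)], collapse = "")
  }
  prev_end <- 0L
  offset <- 0L
  for (i in seq_len(n_ops)) {
    rs <- top$ref_start[i]; re <- top$ref_end[i]
    if (rs > prev_end + 1L) {
      np <- np + 1L
      pieces[np] <- substring(seq, prev_end + 1L, rs - 1L)
      add_seg(prev_end + 1L, rs - 1L, offset, FALSE, NA_integer_)
    }
    span <- re - rs + 1L
    kind <- top$kind[i]
    if (kind == "insertion") {
      np <- np + 1L
      pieces[np] <- top$piece[i]
      offset <- offset + nchar(top$piece[i])
      prev_end <- re  # == rs - 1, empty reference span
    } else if (kind == "deletion" || kind == "cnv_loss") {
      add_seg(rs, re, 0L, TRUE, max(rs - 1L + offset, 0L))
      offset <- offset - span
      prev_end <- re
    } else {  # cnv_gain: tandem copies, each carrying the contained indels;
              # reference positions map into the first copy
      sub <- iop[!is.na(container) & container == top$cnv_idx[i], , drop = FALSE]
      copy <- assemble_span(rs, re, sub, offset, map_first_copy = TRUE)
      np <- np + 1L
      pieces[np] <- strrep(copy, top$cn[i])
      offset <- offset + top$cn[i] * nchar(copy) - span
      prev_end <- re
    }
  }
  if (prev_end < len) {
    np <- np + 1L
    pieces[np] <- substring(seq, prev_end + 1L, len)
    add_seg(prev_end + 1L, len, offset, FALSE, NA_integer_)
  }
  if (ns == 0L) {
    coord_map <- data.frame(ref_start = 1L, ref_end = len, offset = 0L,
                            deleted = FALSE, left_pos = NA_integer_)
  } else {
    idx <- seq_len(ns)
    coord_map <- data.frame(ref_start = seg_start[idx], ref_end = seg_end[idx],
                            offset = seg_off[idx], deleted = seg_del[idx],
                            left_pos = seg_left[idx])
  }
  pieces <- pieces[seq_len(np)]
  structure(
    list(chrom = chrom, allele = allele,
         sequence = paste0(pieces, collapse = ""),
         coord_map = coord_map),
    class = "allele_seq"
  )
}

#' Map reference coordinates to allele coordinates
#'
#' Positions inside a deleted span (deletion or CNV loss) map to the allele
#' coordinate of the deletion's left edge (0 when the deletion starts at the
#' first base). With no variants applied the map is the identity.
#'
#' @param allele_seq An `allele_seq` from [apply_variants()].
#' @param pos Integer vector of 1-based reference positions.
#' @return Integer vector of 1-based allele positions.
#' @export
map_ref_to_allele <- function(allele_seq, pos) {
  cm <- allele_seq$coord_map
  if (any(pos < 1L | pos > cm$ref_end[nrow(cm)])) stop("position outside chromosome")
  i <- findInterval(pos, cm$ref_start)
  ifelse(cm$deleted[i], cm$left_pos[i], pos + cm$offset[i])
}

#' Write allele sequences to FASTA
#'
#' Headers are `<chrom>_allele<k>`; lines wrap at `width` characters.
#'
#' @param alleles List of `allele_seq` objects (may be empty).
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(alleles, `[[`, "", "sequence"))
  names(seqs) <- vapply(alleles, function(a) paste0(a$chrom, "_allele", a$allele), "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
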