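`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a parent seed
#'
#' Deterministic integer mixing used to give every module / worker block its
#' own reproducible random stream from one global seed. Results stay inside
#' the 32-bit signed range R requires of [set.seed()].
#'
#' @param seed Integer parent seed.
#' @param index Integer stream index (module id, worker block, replicate).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 7919) %% 2147483629)
}

# Membership of 1-based positions in sorted disjoint 0-based half-open intervals.
positions_in_intervals <- function(pos, intervals) {
  if (length(pos) == 0L) return(logical(0))
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos - 1L, intervals$start)
  idx >= 1L & (pos - 1L) < intervals$end[pmax(idx, 1L)]
}

# Overlap of 1-based inclusive spans [start, end] with sorted disjoint
# 0-based half-open intervals. Disjoint sorted intervals have increasing
# ends, so only the last interval starting at or before `end - 1` can hit.
spans_overlap_intervals <- function(start, end, intervals) {
  if (length(start) == 0L) return(logical(0))
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(start)))
  idx <- findInterval(end - 1L, intervals$start)
  idx >= 1L & intervals$end[pmax(idx, 1L)] > (start - 1L)
}

# Largest-remainder apportionment of n across fractions (ties broken by
# position, so the result is deterministic).
largest_remainder <- function(n, fracs) {
  stopifnot(abs(sum(fracs) - 1) < 1e-9, n >= 0)
  exact <- n * fracs
  base <- floor(exact)
  short <- as.integer(round(n - sum(base)))
  if (short > 0L) {
    ord <- order(-(exact - base), seq_along(fracs))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Uniform integer draws on [lo, hi]; safe when lo == hi (unlike sample(lo:hi)).
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Vectorized reverse complement on plain character vectors (N-aware).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random ACGT strings of the given lengths, carved out of one bulk draw.
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  big <- paste0(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1L, ends)
}
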