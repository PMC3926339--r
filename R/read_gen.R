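#' Read generation parameters
#'
#' Insert size here means the INNER DISTANCE between the two mates (the gap
#' between the 3' ends), not the fragment length: fragment length =
#' 2 x read_length + inner distance. Tools disagree on this convention, so it
#' is stated prominently. Reads are drawn from the realized allele sequences
#' (post-variant), so allele fraction and CNV depth signal emerge naturally.
#'
#' @param coverage Fold coverage over the total allele length (e.g. 15).
#' @param read_length Read length in bases (>= 20, default 100).
#' @param paired Paired-end flag (default `TRUE`).
#' @param insert_mean,insert_sd Mean / SD of the inner distance in bases;
#'   draws are rounded and floored at 0. Ignored in single-end mode.
#' @param workers Number of concurrent workers, 1-4. Output is always
#'   partitioned into 4 fixed blocks with independent derived random
#'   streams, so the concatenated output is byte-identical for any worker
#'   count; `workers` only sets how many blocks run in parallel.
#' @param strand_flip When `TRUE` (default) each fragment is sequenced from
#'   a random strand, balancing variant strands across reads.
#' @param gzip Write gzipped FASTQ.
#' @param seed Optional integer seed; every random stream in
#'   [generate_reads()] derives from it.
#' @return A list of class `read_gen_config`.
#' @export
read_gen_config <- function(coverage = 15, read_length = 100L, paired = TRUE,
                            insert_mean = 100, insert_sd = 20, workers = 1L,
                            strand_flip = TRUE, gzip = FALSE, seed = NULL) {
  stopifnot(coverage > 0, read_length >= 20, insert_mean >= 0, insert_sd >= 0,
            workers >= 1, workers <= 4)
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 paired = paired, insert_mean = insert_mean, insert_sd = insert_sd,
                 workers = as.integer(workers), strand_flip = strand_flip,
                 gzip = gzip, seed = seed),
            class = "read_gen_config")
}

#' Number of read pairs (or reads) for a target coverage
#'
#' The standard coverage identity: paired,
#' `N = round(coverage * total_allele_length / (2 * read_length))` pairs;
#' single-end, `N = round(coverage * total_allele_length / read_length)`
#' reads. `total_allele_length` sums BOTH allele sequences; reads are later
#' split across alleles proportionally to length.
#'
#' @param coverage Fold coverage.
#' @param total_allele_length Summed length of all allele sequences.
#' @param read_length Read length.
#' @param paired Paired-end flag.
#' @return Integer count (0 with a warning if the request rounds to zero).
#' @export
compute_pair_count <- function(coverage, total_allele_length, read_length,
                               paired = TRUE) {
  n <- round(coverage * total_allele_length / ((if (paired) 2 else 1) * read_length))
  if (n == 0) warning("requested coverage rounds to zero reads")
  as.integer(n)
}

#' Draw fragment intervals on an allele sequence
#'
#' Paired mode: inner distance `d ~ round(Normal(insert_mean, insert_sd))`
#' floored at 0, fragment length `F = 2 * read_length + d`, start uniform
#' over the valid range; fragments longer than the allele are redrawn
#' (bounded retries, then an error). Single-end mode: `F = read_length`.
#'
#' @param allele_length Length of the allele sequence.
#' @param cfg A [read_gen_config()].
#' @param n Number of fragments.
#' @return data.frame with 1-based `start` and `len` columns.
#' @export
draw_fragment <- function(allele_length, cfg = read_gen_config(), n = 1L) {
  L <- cfg$read_length
  min_len <- if (cfg$paired) 2L * L else L
  if (allele_length < min_len) {
    stop("allele sequence (", allele_length, " bases) shorter than the minimum ",
         "fragment (", min_len, " bases)")
  }
  if (!cfg$paired) {
    flen <- rep(L, n)
  } else {
    flen <- 2L * L + pmax(round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)), 0)
    for (i in seq_len(100L)) {
      bad <- flen > allele_length
      if (!any(bad)) break
      flen[bad] <- 2L * L +
        pmax(round(stats::rnorm(sum(bad), cfg$insert_mean, cfg$insert_sd)), 0)
    }
    if (any(flen > allele_length)) {
      stop("could not draw fragments shorter than the allele; ",
           "reduce insert_mean/insert_sd")
    }
  }
  start <- floor(stats::runif(n) * (allele_length - flen + 1)) + 1L
  data.frame(start = as.integer(start), len = as.integer(flen))
}

.BASES <- c(65L, 67L, 71L, 84L)  # A C G T
.ALTMAT <- rbind(c(67L, 71L, 84L), c(65L, 71L, 84L),
                 c(65L, 67L, 84L), c(65L, 67L, 71L))

# Vectorized quality-driven substitution errors. seqs: equal-length reads;
# qmat: matching integer Phred matrix. N bases are never substituted.
.inject_errors_matrix <- function(seqs, qmat) {
  n <- length(seqs)
  if (n == 0L) return(seqs)
  L <- ncol(qmat)
  flat <- utf8ToInt(paste0(seqs, collapse = ""))
  p <- phred_error_prob(as.vector(t(qmat)))
  hit <- stats::runif(n * L) < p & flat != 78L  # 78 = N
  if (any(hit)) {
    base_i <- match(flat[hit], .BASES)
    alt_i <- sample.int(3L, sum(hit), replace = TRUE)
    flat[hit] <- .ALTMAT[cbind(base_i, alt_i)]
  }
  big <- intToUtf8(flat)
  substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

#' Inject substitution sequencing errors into a read
#'
#' Position `i` is substituted with probability `10^(-q_i / 10)` (its Phred
#' error probability), uniformly to one of the other three bases. N bases
#' pass through untouched. Uses the current RNG stream.
#'
#' @param seq Read sequence (one string).
#' @param qual Sanger-encoded quality string of the same length.
#' @return The mutated sequence.
#' @export
inject_errors <- function(seq, qual) {
  stopifnot(nchar(seq) == nchar(qual))
  .inject_errors_matrix(seq, decode_phred(qual))
}

# Generate all reads of one (sequence, block) unit. Returns list of
# name/seq/qual vectors (mate2 entries NULL in single-end mode).
.gen_unit <- function(aseq, n, profile, cfg, start_index) {
  L <- cfg$read_length
  slen <- nchar(aseq$sequence)
  frag <- draw_fragment(slen, cfg, n)
  flip <- if (cfg$strand_flip) stats::runif(n) < 0.5 else rep(FALSE, n)
  fs <- frag$start
  fe <- frag$start + frag$len - 1L
  left <- substring(aseq$sequence, fs, fs + L - 1L)
  idx <- start_index + seq_len(n) - 1L
  names <- paste0("frag", idx, ":", aseq$chrom, ":", aseq$allele, ":", fs, ":", fe)
  if (!cfg$paired) {
    seq1 <- ifelse(flip, revcomp(left), left)
    q1 <- sample_quality_matrix(profile, 1L, n)
    list(name = names, seq1 = .inject_errors_matrix(seq1, q1),
         qual1 = encode_phred(q1), seq2 = NULL, qual2 = NULL)
  } else {
    rc_right <- revcomp(substring(aseq$sequence, fe - L + 1L, fe))
    seq1 <- ifelse(flip, rc_right, left)
    seq2 <- ifelse(flip, left, rc_right)
    q1 <- sample_quality_matrix(profile, 1L, n)
    seq1 <- .inject_errors_matrix(seq1, q1)
    q2 <- sample_quality_matrix(profile, 2L, n)
    seq2 <- .inject_errors_matrix(seq2, q2)
    list(name = names, seq1 = seq1, qual1 = encode_phred(q1),
         seq2 = seq2, qual2 = encode_phred(q2))
  }
}

.N_BLOCKS <- 4L

#' Generate reads over realized allele sequences
#'
#' The total read-pair count from [compute_pair_count()] is apportioned
#' across allele sequences by length (largest remainder) and then split into
#' 4 fixed blocks, each owning an independent random stream derived from
#' `cfg$seed`. Blocks are executed with up to `cfg$workers` processes and
#' written in block order, so output bytes are identical whatever the worker
#' count. Read names encode the ground truth
#' (`frag<index>:<chrom>:<allele>:<fragment start>:<fragment end>` in allele
#' coordinates, plus `/1`/`/2` in paired mode), enabling alignment-free
#' evaluation; see [parse_read_names()].
#'
#' @param alleles List of `allele_seq` objects (typically the concatenation
#'   of [apply_variants()] for alleles 1 and 2).
#' @param profile A `quality_profile` with `read_length` equal to
#'   `cfg$read_length` (and two mates in paired mode).
#' @param cfg A [read_gen_config()].
#' @param out_prefix Output path prefix: paired mode writes
#'   `<prefix>_1.fastq` and `<prefix>_2.fastq` (plus `.gz` if `cfg$gzip`),
#'   single-end `<prefix>.fastq`.
#' @return Invisibly, a list with `paths`, `n_units` (pairs or reads) and
#'   `total_bases`.
#' @export
generate_reads <- function(alleles, profile, cfg, out_prefix) {
  stopifnot(inherits(profile, "quality_profile"), inherits(cfg, "read_gen_config"))
  if (profile$read_length != cfg$read_length) {
    stop("profile read_length (", profile$read_length,
         ") does not match cfg read_length (", cfg$read_length, ")")
  }
  if (cfg$paired && length(profile$mates) < 2L) {
    stop("paired-end generation needs a two-mate profile")
  }
  lens <- vapply(alleles, function(a) nchar(a$sequence), numeric(1))
  if (any(lens == 0)) stop("zero-length allele sequence")
  total_len <- sum(lens)
  n_total <- compute_pair_count(cfg$coverage, total_len, cfg$read_length, cfg$paired)
  per_seq <- largest_remainder(n_total, lens / total_len)
  # counts[block, seq]: per-seq counts split across the 4 fixed blocks
  counts <- vapply(per_seq, function(ns) {
    base <- rep(ns %/% .N_BLOCKS, .N_BLOCKS)
    extra <- ns %% .N_BLOCKS
    base + (seq_len(.N_BLOCKS) <= extra)
  }, integer(.N_BLOCKS))
  counts <- matrix(counts, nrow = .N_BLOCKS)
  # global pair indices follow write order: block-major, sequence-minor
  offsets <- matrix(cumsum(as.integer(t(counts))) - as.integer(t(counts)),
                    ncol = .N_BLOCKS)
  seed0 <- cfg$seed %||% 0L
  run_block <- function(b) {
    set.seed(derive_seed(seed0, 1000L + b))
    units <- lapply(seq_along(alleles), function(si) {
      if (counts[b, si] == 0L) return(NULL)
      .gen_unit(alleles[[si]], counts[b, si], profile, cfg,
                start_index = offsets[si, b] + 1L)
    })
    units <- units[!vapply(units, is.null, logical(1))]
    list(name = unlist(lapply(units, `[[`, "name")),
         seq1 = unlist(lapply(units, `[[`, "seq1")),
         qual1 = unlist(lapply(units, `[[`, "qual1")),
         seq2 = unlist(lapply(units, `[[`, "seq2")),
         qual2 = unlist(lapply(units, `[[`, "qual2")))
  }
  blocks <- if (cfg$workers > 1L) {
    parallel::mclapply(seq_len(.N_BLOCKS), run_block, mc.cores = cfg$workers)
  } else {
    lapply(seq_len(.N_BLOCKS), run_block)
  }
  pull <- function(field) unlist(lapply(blocks, `[[`, field))
  ext <- if (cfg$gzip) ".fastq.gz" else ".fastq"
  if (cfg$paired) {
    paths <- paste0(out_prefix, c("_1", "_2"), ext)
    .write_fastq(paste0(pull("name"), "/1"), pull("seq1"), pull("qual1"),
                 paths[1], cfg$gzip)
    .write_fastq(paste0(pull("name"), "/2"), pull("seq2"), pull("qual2"),
                 paths[2], cfg$gzip)
    total_bases <- 2 * n_total * cfg$read_length
  } else {
    paths <- paste0(out_prefix, ext)
    .write_fastq(pull("name"), pull("seq1"), pull("qual1"), paths, cfg$gzip)
    total_bases <- n_total * cfg$read_length
  }
  invisible(list(paths = paths, n_units = n_total, total_bases = total_bases))
}

.write_fastq <- function(names, seqs, quals, path, gzip = FALSE) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- names
  Biostrings::writeQualityScaledXStringSet(x, path, compress = gzip)
  invisible(path)
}

#' Decode read-name provenance
#'
#' Parses names of the form
#' `frag<index>:<chrom>:<allele>:<start>:<end>[/mate]` back into the exact
#' fragment coordinates (allele coordinate space) used to generate the read.
#'
#' @param names Character vector of read names.
#' @return data.frame with `index`, `chrom`, `allele`, `start`, `end`,
#'   `mate` (NA for single-end reads).
#' @export
parse_read_names <- function(names) {
  mate <- ifelse(grepl("/[12]$", names), as.integer(sub(".*/", "", names)), NA_integer_)
  core <- sub("/[12]$", "", names)
  parts <- strsplit(core, ":", fixed = TRUE)
  if (any(lengths(parts) != 5L)) stop("unparseable read name(s)")
  m <- do.call(rbind, parts)
  data.frame(index = as.integer(sub("^frag", "", m[, 1])), chrom = m[, 2],
             allele = as.integer(m[, 3]), start = as.integer(m[, 4]),
             end = as.integer(m[, 5]), mate = mate)
}
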