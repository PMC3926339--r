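#' Generate a synthetic reference genome
#'
#' Random ACGT chromosomes with optional embedded N-runs, emulating the
#' assembly gaps of real references. N-runs of length uniform in
#' `n_run_range` are placed uniformly (overlaps allowed) until roughly
#' `n_fraction` of each chromosome is N, so the realized N fraction is
#' approximate. Base composition is uniform; real genomes' GC structure and
#' repeats are deliberately not modelled.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_fraction Approximate fraction of each chromosome covered by
#'   N-runs (default 0).
#' @param n_run_range Min/max N-run length in bases.
#' @param seed Optional integer seed.
#' @return A `ref_genome`.
#' @export
simulate_reference_genome <- function(chrom_lengths = c(chr1 = 1e6),
                                      n_fraction = 0,
                                      n_run_range = c(100L, 1000L),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(names(chrom_lengths)), n_fraction >= 0, n_fraction < 1)
  seqs <- vapply(chrom_lengths, function(len) {
    s <- random_dna(len)
    if (n_fraction > 0) {
      placed <- 0
      while (placed < n_fraction * len) {
        run <- sample_range(n_run_range[1], n_run_range[2], 1L)
        at <- sample_range(1L, max(len - run + 1L, 1L), 1L)
        substr(s, at, at + run - 1L) <- strrep("N", run)
        placed <- placed + run
      }
    }
    s
  }, "")
  ref_genome(seqs)
}

#' Per-cycle Phred distribution of the synthetic training model
#'
#' The synthetic trainer emulates an Illumina-like quality decay: the mean
#' Phred score declines linearly from `q_start` (cycle 1) to `q_end` (last
#' cycle), mate 2 shifted down by `mate2_penalty`; each cycle's distribution
#' is a normal with SD `q_sd` discretized onto Q0..Q41. This function
#' returns the exact distribution, used as the ground truth when testing
#' that profile building recovers it.
#'
#' @param read_length Cycles.
#' @param mate Mate index (1 or 2).
#' @param q_start,q_end Mean Phred at the first/last cycle for mate 1.
#' @param q_sd Per-cycle SD of the discretized normal.
#' @param mate2_penalty Mean shift (Phred) subtracted for mate 2.
#' @return `read_length` x 42 matrix of per-cycle probabilities over Q0..Q41.
#' @export
training_quality_model <- function(read_length = 100L, mate = 1L,
                                   q_start = 37, q_end = 25, q_sd = 4,
                                   mate2_penalty = 2) {
  mu <- seq(q_start, q_end, length.out = read_length) -
    if (mate == 2L) mate2_penalty else 0
  t(vapply(mu, function(m) {
    p <- stats::pnorm(0:42 - 0.5, m, q_sd)
    d <- diff(p)
    d[1] <- d[1] + p[1]                     # mass below Q0 folds into Q0
    d[42] <- d[42] + 1 - p[43]              # mass above Q41 folds into Q41
    d / sum(d)
  }, numeric(42)))
}

#' Generate a synthetic training FASTQ pair
#'
#' Reads have uniform-random ACGT sequences (content is irrelevant for
#' quality training) and qualities drawn per cycle from
#' [training_quality_model()]. Intended to stand in for real Illumina
#' training data in tests and examples; it reproduces the per-cycle quality
#' decay but none of the sequence-dependent structure of a real run.
#'
#' @param out_r1 Output path for mate 1.
#' @param out_r2 Optional output path for mate 2 (omit for single-end).
#' @param n_reads Number of reads per mate.
#' @param read_length Read length.
#' @param seed Optional integer seed.
#' @param ... Passed to [training_quality_model()].
#' @return The written paths, invisibly.
#' @export
simulate_training_fastq <- function(out_r1, out_r2 = NULL, n_reads = 10000L,
                                    read_length = 100L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  paths <- c(out_r1, out_r2)
  for (m in seq_along(paths)) {
    model <- training_quality_model(read_length, mate = m, ...)
    q <- matrix(0L, nrow = n_reads, ncol = read_length)
    for (cyc in seq_len(read_length)) {
      q[, cyc] <- sample.int(42L, n_reads, replace = TRUE, prob = model[cyc, ]) - 1L
    }
    .write_fastq(paste0("train", seq_len(n_reads), if (length(paths) == 2L)
                          paste0("/", m) else ""),
                 random_dna(rep(read_length, n_reads)), encode_phred(q),
                 paths[m], gzip = grepl("\\.gz$", paths[m]))
  }
  invisible(paths)
}
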