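#' Build an empirical per-cycle Phred quality profile from training FASTQ
#'
#' For each mate and each sequencing cycle, the observed Sanger-encoded
#' (Phred+33) quality scores are histogrammed over Q0..Q41 and normalized to
#' a probability vector. Reads longer than `read_length` are truncated;
#' shorter reads are skipped and counted. Quality strings sampled from the
#' profile later reproduce these per-cycle distributions; draws across
#' cycles are independent.
#'
#' @param fastq_r1 Path to mate-1 FASTQ (plain or gzipped, Sanger encoding).
#' @param fastq_r2 Optional path to mate-2 FASTQ; omit for a single-end
#'   profile.
#' @param read_length Number of cycles the profile covers.
#' @return An object of class `quality_profile`: `read_length`, `mates`
#'   (list of `read_length` x 42 probability matrices, columns Q0..Q41),
#'   `training_reads` and `skipped_reads` per mate.
#' @export
build_quality_profile <- function(fastq_r1, fastq_r2 = NULL, read_length = 100L) {
  read_length <- as.integer(read_length)
  stopifnot(read_length > 0L)
  paths <- c(fastq_r1, fastq_r2)
  mates <- vector("list", length(paths))
  used <- skipped <- integer(length(paths))
  for (m in seq_along(paths)) {
    reads <- Biostrings::readDNAStringSet(paths[m], format = "fastq",
                                          with.qualities = TRUE)
    quals <- as.character(S4Vectors::mcols(reads)$qualities)
    long_enough <- nchar(quals) >= read_length
    skipped[m] <- sum(!long_enough)
    quals <- substr(quals[long_enough], 1L, read_length)
    used[m] <- length(quals)
    if (used[m] == 0L) stop("no usable reads (>= ", read_length, " cycles) in ", paths[m])
    q <- matrix(utf8ToInt(paste0(quals, collapse = "")) - 33L,
                ncol = read_length, byrow = TRUE)
    if (any(q > 41L) || any(q < 0L)) {
      offender <- which(apply(q > 41L | q < 0L, 1L, any))[1L]
      stop("non-Sanger quality encoding in ", paths[m], ", record ",
           which(long_enough)[offender])
    }
    probs <- t(apply(q, 2L, function(col) tabulate(col + 1L, nbins = 42L)))
    mates[[m]] <- probs / rowSums(probs)
  }
  structure(list(read_length = read_length, mates = mates,
                 training_reads = used, skipped_reads = skipped),
            class = "quality_profile")
}

#' @exportS3Method base::print
print.quality_profile <- function(x, ...) {
  cat("quality_profile:", x$read_length, "cycles,", length(x$mates),
      "mate(s), trained on", paste(x$training_reads, collapse = "/"),
      "reads\n")
  invisible(x)
}

#' Sample a quality matrix from a profile
#'
#' One independent draw per cycle from that cycle's empirical distribution.
#'
#' @param profile A `quality_profile`.
#' @param mate Mate index (1 or 2); requesting mate 2 of a single-end
#'   profile is an error.
#' @param n Number of reads to draw.
#' @return Integer matrix `n` x `read_length` of Phred scores.
#' @export
sample_quality_matrix <- function(profile, mate = 1L, n = 1L) {
  if (mate > length(profile$mates)) {
    stop("profile has no mate ", mate, " (single-end profile?)")
  }
  probs <- profile$mates[[mate]]
  out <- matrix(0L, nrow = n, ncol = profile$read_length)
  for (cyc in seq_len(profile$read_length)) {
    out[, cyc] <- sample.int(42L, n, replace = TRUE, prob = probs[cyc, ]) - 1L
  }
  out
}

#' Sample one quality string from a profile
#'
#' @inheritParams sample_quality_matrix
#' @return A Sanger-encoded (Phred+33) quality string of `read_length`
#'   characters.
#' @export
sample_quality_string <- function(profile, mate = 1L) {
  encode_phred(sample_quality_matrix(profile, mate, 1L))[1L]
}

# Integer Phred matrix -> Sanger (+33) strings, one per row.
encode_phred <- function(q) {
  n <- nrow(q)
  if (n == 0L) return(character(0))
  flat <- intToUtf8(t(q) + 33L)
  substring(flat, (seq_len(n) - 1L) * ncol(q) + 1L, seq_len(n) * ncol(q))
}

# Sanger strings -> integer Phred matrix.
decode_phred <- function(strings) {
  if (length(strings) == 0L) return(matrix(0L, 0L, 0L))
  L <- nchar(strings[1L])
  matrix(utf8ToInt(paste0(strings, collapse = "")) - 33L, ncol = L, byrow = TRUE)
}

#' Phred score to error probability
#'
#' `p = 10^(-q / 10)`: Q20 is 1 error in 100, Q30 is 1 in 1000, Q0 is
#' certainty of error.
#'
#' @param q Numeric vector of Phred scores.
#' @return Error probabilities.
#' @export
phred_error_prob <- function(q) 10^(-q / 10)

#' Write a quality profile to its plain-text file format
#'
#' Header lines `#read_length`, `#mates`, `#training_reads`, then one line
#' per (mate, cycle): mate, cycle (0-based), and 42 tab-separated
#' probabilities for Q0..Q41, printed at full precision so the round-trip
#' through [read_quality_profile()] is lossless.
#'
#' @param profile A `quality_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#read_length\t", profile$read_length),
               paste0("#mates\t", length(profile$mates)),
               paste0("#training_reads\t",
                      paste(profile$training_reads, collapse = "\t"))), con)
  for (m in seq_along(profile$mates)) {
    probs <- profile$mates[[m]]
    for (cyc in seq_len(profile$read_length)) {
      writeLines(paste(c(m, cyc - 1L, sprintf("%.17g", probs[cyc, ])),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a quality profile written by [write_quality_profile()]
#'
#' @param path Profile file path.
#' @return A `quality_profile`.
#' @export
read_quality_profile <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    ln <- header[startsWith(header, paste0("#", key))]
    if (length(ln) != 1L) stop("malformed profile file: missing #", key)
    strsplit(ln, "\t")[[1]][-1]
  }
  read_length <- as.integer(get("read_length"))
  n_mates <- as.integer(get("mates"))
  training <- as.integer(get("training_reads"))
  fields <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (ncol(fields) != 44L) stop("malformed profile line(s): expected 44 fields")
  mates <- lapply(seq_len(n_mates), function(m) {
    rows <- fields[fields[, 1] == m, , drop = FALSE]
    rows <- rows[order(rows[, 2]), , drop = FALSE]
    if (nrow(rows) != read_length) stop("profile mate ", m, " has wrong cycle count")
    unname(rows[, 3:44, drop = FALSE])
  })
  structure(list(read_length = read_length, mates = mates,
                 training_reads = training,
                 skipped_reads = rep(NA_integer_, n_mates)),
            class = "quality_profile")
}
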