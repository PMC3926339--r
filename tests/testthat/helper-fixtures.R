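# Shared fixtures, generated in code and cached for the test session.

# 1 Mb two-chromosome genome with ~5% N-runs.
test_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_reference_genome(c(chrA = 6e5, chrB = 4e5),
                                          n_fraction = 0.05, seed = 424242)
    }
    cache
  }
})

# Paired 100-cycle quality profile trained on synthetic FASTQ.
test_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r1 <- tempfile(fileext = "_1.fastq")
      r2 <- tempfile(fileext = "_2.fastq")
      simulate_training_fastq(r1, r2, n_reads = 5000, seed = 90211)
      cache <<- build_quality_profile(r1, r2, 100L)
      unlink(c(r1, r2))
    }
    cache
  }
})

# Write a FASTA from raw lines (for parser edge cases).
write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Total variation distance between two probability vectors.
tv_distance <- function(p, q) 0.5 * sum(abs(p - q))
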