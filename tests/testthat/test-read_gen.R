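test_that("pair counts follow the coverage identity", {
  expect_equal(compute_pair_count(15, 2e6, 100, paired = TRUE), 150000L)
  expect_equal(compute_pair_count(15, 2e6, 100, paired = FALSE), 300000L)
  expect_warning(n0 <- compute_pair_count(1e-4, 1000, 100, paired = TRUE),
                 "zero")
  expect_equal(n0, 0L)
})

test_that("fragments follow the inner-distance geometry", {
  cfg <- read_gen_config(insert_mean = 100, insert_sd = 0, seed = 1)
  set.seed(81)
  f <- draw_fragment(10000L, cfg, n = 50L)
  expect_true(all(f$len == 300L))                # 2 x 100 + 100
  f2 <- draw_fragment(300L, cfg, n = 20L)
  expect_true(all(f2$start == 1L))               # allele length == fragment
  expect_error(draw_fragment(150L, cfg), "shorter")
  cfg_sd <- read_gen_config(insert_mean = 150, insert_sd = 30)
  d <- draw_fragment(1e6L, cfg_sd, n = 1e5L)$len - 200L
  expect_lt(abs(mean(d) - 150), 3 * stats::sd(d) / sqrt(length(d)))
  # single-end fragments are exactly one read long
  expect_true(all(draw_fragment(1000L, read_gen_config(paired = FALSE),
                                n = 10L)$len == 100L))
})

test_that("error injection follows the Phred error probabilities", {
  set.seed(82)
  # p = 1 limit: Q0 everywhere forces a substitution at every non-N position
  out <- inject_errors(strrep("A", 50), strrep("!", 50))
  expect_false(grepl("A", out))
  expect_equal(nchar(out), 50L)
  # N passthrough: never substituted even at p = 1
  out_n <- inject_errors("ANAN", "!!!!")
  expect_equal(substring(out_n, 2, 2), "N")
  expect_equal(substring(out_n, 4, 4), "N")
  expect_false(substring(out_n, 1, 1) == "A")
  # Q41 binomial oracle over 10^6 bases
  n_reads <- 10000L
  seqs <- random_dna(rep(100L, n_reads))
  qual <- strrep("J", 100)  # Q41
  mutated <- vapply(seqs, inject_errors, "", qual = qual, USE.NAMES = FALSE)
  errs <- sum(utf8ToInt(paste0(seqs, collapse = "")) !=
                utf8ToInt(paste0(mutated, collapse = "")))
  expected <- 1e6 * 10^(-4.1)
  expect_lt(abs(errs - expected), 3 * sqrt(expected))
})

test_that("read pairs carry provenance names, matched mates and correct strands", {
  g <- simulate_reference_genome(c(chr1 = 5e4), seed = 83)
  alleles <- c(apply_variants(g, allele = 1L), apply_variants(g, allele = 2L))
  prefix <- tempfile()
  info <- generate_reads(alleles, test_profile(),
                         read_gen_config(coverage = 3, seed = 84), prefix)
  r1 <- Biostrings::readDNAStringSet(info$paths[1], format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(info$paths[2], format = "fastq",
                                     with.qualities = TRUE)
  expect_equal(length(r1), info$n_units)
  expect_equal(length(r2), info$n_units)
  nm1 <- parse_read_names(names(r1))
  nm2 <- parse_read_names(names(r2))
  expect_equal(nm1$mate, rep(1L, length(r1)))
  expect_equal(nm2$mate, rep(2L, length(r2)))
  expect_identical(nm1[c("index", "chrom", "allele", "start", "end")],
                   nm2[c("index", "chrom", "allele", "start", "end")])
  expect_equal(nm1$index, seq_len(length(r1)))
  expect_true(all(nm1$start >= 1L & nm1$end <= 5e4))
  expect_true(all(nm1$end - nm1$start + 1L >= 200L))
  expect_true(all(Biostrings::width(r1) == 100L))
  # names decode to the exact fragment: one mate matches the fragment start,
  # the other the reverse complement of the fragment end (modulo rare
  # injected errors, so require < 3% mismatched bases)
  i <- 1L
  frag_start <- substring(g$chromosomes[["chr1"]], nm1$start[i], nm1$start[i] + 99L)
  frag_end_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(g$chromosomes[["chr1"]], nm1$end[i] - 99L,
                                    nm1$end[i]))))
  mism <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  direct <- mism(as.character(r1[[i]]), frag_start) +
    mism(as.character(r2[[i]]), frag_end_rc)
  flipped <- mism(as.character(r1[[i]]), frag_end_rc) +
    mism(as.character(r2[[i]]), frag_start)
  expect_lt(min(direct, flipped), 6L)
})

test_that("emitted coverage matches the request within rounding", {
  g <- simulate_reference_genome(c(chr1 = 4e4), seed = 85)
  alleles <- c(apply_variants(g, allele = 1L), apply_variants(g, allele = 2L))
  info <- generate_reads(alleles, test_profile(),
                         read_gen_config(coverage = 7.5, seed = 86), tempfile())
  expect_lt(abs(info$total_bases / 8e4 - 7.5) / 7.5, 0.01)
})

test_that("output bytes are invariant to the worker count", {
  g <- simulate_reference_genome(c(chr1 = 3e4, chr2 = 2e4), seed = 87)
  alleles <- c(apply_variants(g, allele = 1L), apply_variants(g, allele = 2L))
  p1 <- tempfile(); p2 <- tempfile()
  generate_reads(alleles, test_profile(), read_gen_config(coverage = 2, seed = 88,
                                                          workers = 1), p1)
  generate_reads(alleles, test_profile(), read_gen_config(coverage = 2, seed = 88,
                                                          workers = 4), p2)
  for (m in 1:2) {
    expect_identical(unname(tools::md5sum(paste0(p1, "_", m, ".fastq"))),
                     unname(tools::md5sum(paste0(p2, "_", m, ".fastq"))))
  }
})

test_that("single-end mode writes one FASTQ without mate suffixes", {
  g <- simulate_reference_genome(c(chr1 = 2e4), seed = 89)
  alleles <- c(apply_variants(g, allele = 1L), apply_variants(g, allele = 2L))
  info <- generate_reads(alleles, test_profile(),
                         read_gen_config(coverage = 2, paired = FALSE, seed = 90),
                         tempfile())
  expect_equal(length(info$paths), 1L)
  reads <- Biostrings::readDNAStringSet(info$paths, format = "fastq")
  expect_true(all(is.na(parse_read_names(names(reads))$mate)))
  expect_equal(length(reads), info$n_units)
})

test_that("profile/config mismatches are rejected", {
  g <- simulate_reference_genome(c(chr1 = 2e4), seed = 91)
  alleles <- apply_variants(g, allele = 1L)
  expect_error(generate_reads(alleles, test_profile(),
                              read_gen_config(coverage = 1, read_length = 50),
                              tempfile()),
               "read_length")
})

test_that("homozygous tandem gains triple read depth over the gained span", {
  g <- simulate_reference_genome(c(chr1 = 1e5), seed = 92)
  gain <- data.frame(chrom = "chr1", start = 40001L, end = 60000L, size = 20000L,
                     cn_allele1 = 3L, cn_allele2 = 3L)
  alleles <- c(apply_variants(g, cnvs = gain, allele = 1L),
               apply_variants(g, cnvs = gain, allele = 2L))
  info <- generate_reads(alleles, test_profile(),
                         read_gen_config(coverage = 30, seed = 93), tempfile())
  r1 <- Biostrings::readDNAStringSet(info$paths[1], format = "fastq")
  nm <- parse_read_names(names(r1))
  # read base intervals in allele coordinates (mate1 at fragment start,
  # mate2 at fragment end)
  starts <- c(nm$start, nm$end - 99L)
  ends <- c(nm$start + 99L, nm$end)
  bases_in <- function(lo, hi) {
    sum(pmax(pmin(ends, hi) - pmax(starts, lo) + 1L, 0L))
  }
  a <- alleles$chr1  # both alleles share the coord map (hom CNV)
  gain_lo <- map_ref_to_allele(a, 40001L)
  gain_depth <- bases_in(gain_lo, gain_lo + 3L * 20000L - 1L) / 20000L
  flank_depth <- bases_in(map_ref_to_allele(a, 1L), map_ref_to_allele(a, 30000L)) /
    30000L
  ratio <- gain_depth / flank_depth
  expect_gt(ratio, 3 * 0.75)
  expect_lt(ratio, 3 * 1.25)
})
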