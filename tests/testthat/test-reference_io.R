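test_that("FASTA parsing normalizes, joins wrapped lines and records N-regions", {
  g <- read_genome_fasta(write_fasta_lines(c(">chr1", "ACGTN")))
  expect_equal(unname(g$chromosomes["chr1"]), "ACGTN")
  expect_equal(g$n_regions$chr1, data.frame(start = 4L, end = 5L))

  g <- read_genome_fasta(write_fasta_lines(c(">chr1", "acgt")))
  expect_equal(unname(g$chromosomes["chr1"]), "ACGT")
  expect_equal(nrow(g$n_regions$chr1), 0L)

  g <- read_genome_fasta(write_fasta_lines(c(">chr1 description here", "AC", "GT")))
  expect_equal(unname(g$chromosomes["chr1"]), "ACGT")

  # IUPAC ambiguity codes normalize to N
  g <- ref_genome(c(c1 = "ARYT"))
  expect_equal(unname(g$chromosomes["c1"]), "ANNT")

  expect_error(read_genome_fasta(write_fasta_lines(c(">a", "ACGT", ">a", "ACGT"))),
               "duplicate")
  expect_error(ref_genome(c(a = "")), "empty sequence.*a")
})

test_that("find_n_regions returns maximal runs as sorted disjoint intervals", {
  expect_equal(nrow(find_n_regions("ACGT")), 0L)
  expect_equal(find_n_regions("NNACNN"),
               data.frame(start = c(0L, 4L), end = c(2L, 6L)))
  expect_equal(find_n_regions(strrep("N", 10)), data.frame(start = 0L, end = 10L))
  expect_equal(nrow(find_n_regions("")), 0L)
})

test_that("apply_variants realizes SNVs, deletions and tandem CNV gains", {
  g <- ref_genome(c(chr1 = "ACGTACGT"))
  snv <- data.frame(chrom = "chr1", pos = 3L, ref = "G", alt = "A",
                    zygosity = "hom", allele = "both", is_transition = TRUE)
  expect_equal(apply_variants(g, snvs = snv, allele = 1L)$chr1$sequence, "ACATACGT")

  g2 <- ref_genome(c(chr1 = "ACGT"))
  del <- data.frame(chrom = "chr1", pos = 2L, kind = "deletion", length = 2L,
                    seq = "CG", category = "mid", zygosity = "hom", allele = "both")
  a <- apply_variants(g2, indels = del, allele = 1L)$chr1
  expect_equal(a$sequence, "AT")
  expect_equal(map_ref_to_allele(a, 4L), 2L)
  # positions inside the deleted span map to its left edge
  expect_equal(map_ref_to_allele(a, 2L), 1L)
  expect_equal(map_ref_to_allele(a, 3L), 1L)

  gain <- data.frame(chrom = "chr1", start = 1L, end = 2L, size = 2L,
                     cn_allele1 = 3L, cn_allele2 = 1L)
  expect_equal(apply_variants(g2, cnvs = gain, allele = 1L)$chr1$sequence,
               "ACACACGT")
  # allele 2 has copy number 1: untouched
  expect_equal(apply_variants(g2, cnvs = gain, allele = 2L)$chr1$sequence, "ACGT")
})

test_that("apply_variants with no variants is the identity with identity coord_map", {
  g <- test_genome()
  a <- apply_variants(g, allele = 1L)
  expect_identical(a$chrA$sequence, unname(g$chromosomes[["chrA"]]))
  expect_equal(nrow(a$chrA$coord_map), 1L)
  pos <- c(1L, 17L, g$lengths[["chrA"]])
  expect_equal(map_ref_to_allele(a$chrA, pos), pos)
})

test_that("heterozygous variants only touch their assigned allele", {
  g <- ref_genome(c(chr1 = "ACGTACGT"))
  ins <- data.frame(chrom = "chr1", pos = 4L, kind = "insertion", length = 2L,
                    seq = "TT", category = "mid", zygosity = "het", allele = "2")
  expect_equal(apply_variants(g, indels = ins, allele = 1L)$chr1$sequence,
               "ACGTACGT")
  expect_equal(apply_variants(g, indels = ins, allele = 2L)$chr1$sequence,
               "ACGTTTACGT")
})

test_that("gain copies carry contained indels; losses erase them", {
  g <- ref_genome(c(chr1 = "AACCGGTTAACC"))
  ins <- data.frame(chrom = "chr1", pos = 5L, kind = "insertion", length = 1L,
                    seq = "T", category = "single", zygosity = "hom",
                    allele = "both")
  gain <- data.frame(chrom = "chr1", start = 4L, end = 9L, size = 6L,
                     cn_allele1 = 2L, cn_allele2 = 2L)
  a <- apply_variants(g, indels = ins, cnvs = gain, allele = 1L)$chr1
  # span CGGTTA with T inserted after position 5 -> CGTGTTA, twice
  expect_equal(a$sequence, paste0("AAC", "CGTGTTA", "CGTGTTA", "ACC"))
  expect_equal(map_ref_to_allele(a, c(4L, 6L, 10L)), c(4L, 7L, 18L))

  del <- data.frame(chrom = "chr1", pos = 6L, kind = "deletion", length = 2L,
                    seq = "GT", category = "mid", zygosity = "hom",
                    allele = "both")
  loss <- transform(gain, cn_allele1 = 0L, cn_allele2 = 0L)
  b <- apply_variants(g, indels = del, cnvs = loss, allele = 1L)$chr1
  expect_equal(b$sequence, "AACACC")  # contained deletion not removed twice

  straddle <- transform(del, pos = 8L, length = 3L, seq = "TAA")
  expect_error(apply_variants(g, indels = straddle, cnvs = gain, allele = 1L),
               "crosses a CNV boundary")
})

test_that("apply_variants rejects overlapping spans and out-of-range coordinates", {
  g <- ref_genome(c(chr1 = "ACGTACGTACGT"))
  two <- data.frame(chrom = "chr1", pos = c(2L, 4L), kind = "deletion",
                    length = c(4L, 2L), seq = c("CGTA", "TA"),
                    category = "mid", zygosity = "hom", allele = "both")
  expect_error(apply_variants(g, indels = two, allele = 1L), "overlapping")
  far <- data.frame(chrom = "chr1", pos = 10L, kind = "deletion", length = 5L,
                    seq = "NNNNN", category = "mid", zygosity = "hom", allele = "both")
  expect_error(apply_variants(g, indels = far, allele = 1L), "outside")
})

test_that("FASTA write/read round-trips and wraps lines", {
  g <- test_genome()
  alleles <- apply_variants(g, allele = 1L)
  path <- tempfile(fileext = ".fasta")
  write_allele_fasta(alleles, path)
  back <- read_genome_fasta(path)
  expect_equal(names(back$chromosomes), paste0(names(g$chromosomes), "_allele1"))
  expect_identical(unname(back$chromosomes), unname(g$chromosomes))

  a150 <- structure(list(chrom = "c", allele = 1L, sequence = random_150 <-
                           paste(rep("A", 150), collapse = "")), class = "allele_seq")
  write_allele_fasta(list(a150), path)
  lines <- readLines(path)
  expect_equal(lines[1], ">c_allele1")
  expect_equal(nchar(lines[-1]), c(70L, 70L, 10L))

  write_allele_fasta(list(), path)
  expect_equal(length(readLines(path)), 0L)
})

test_that("allele length accounting matches the edit ledger", {
  g <- test_genome()
  ind <- simulate_indels(g, indel_config(n_indels = 400, seed = 99))
  cnv <- simulate_cnvs(g, cnv_config(n_cnvs = 6, size_min = 1000, size_max = 3000,
                                     seed = 100), indels = ind)
  for (k in 1:2) {
    alleles <- apply_variants(g, indels = ind, cnvs = cnv, allele = k)
    sel <- ind$allele %in% c(as.character(k), "both")
    cn <- if (k == 1) cnv$cn_allele1 else cnv$cn_allele2
    # signed length of each applied indel, and the CNV span containing it
    # on this allele (if any)
    delta <- ifelse(ind$kind == "insertion", ind$length, -ind$length)
    iend <- ind$pos + ifelse(ind$kind == "deletion", ind$length - 1L, 0L)
    container <- rep(NA_integer_, nrow(ind))
    for (j in seq_len(nrow(cnv))) {
      if (cn[j] == 1L) next
      inside <- sel & ind$chrom == cnv$chrom[j] & ind$pos >= cnv$start[j] &
        iend <= cnv$end[j] &
        !(ind$kind == "insertion" & ind$pos == cnv$end[j])
      container[inside] <- j
    }
    outside_delta <- sum(delta[sel & is.na(container)])
    cnv_delta <- 0
    for (j in seq_len(nrow(cnv))) {
      if (cn[j] == 0L) {
        cnv_delta <- cnv_delta - cnv$size[j]  # contained indels vanish with it
      } else if (cn[j] >= 2L) {
        copy_len <- cnv$size[j] + sum(delta[!is.na(container) & container == j])
        cnv_delta <- cnv_delta + cn[j] * copy_len - cnv$size[j]
      }
    }
    expected <- sum(g$lengths) + outside_delta + cnv_delta
    expect_equal(sum(vapply(alleles, function(a) nchar(a$sequence), numeric(1))),
                 expected)
  }
})
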