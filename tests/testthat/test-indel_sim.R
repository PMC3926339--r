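test_that("over-generation adds 5% with a ceiling", {
  expect_equal(overgenerate_count(1000), 1050L)
  expect_equal(overgenerate_count(0), 0L)
  expect_equal(overgenerate_count(21), 23L)  # ceil(22.05)
})

test_that("category allocation is exact largest-remainder apportionment", {
  expect_equal(unname(allocate_categories(10000)), c(3000L, 2000L, 4900L, 100L))
  expect_equal(unname(allocate_categories(0)), c(0L, 0L, 0L, 0L))
  # n = 7: floors (2,1,3,0), remainders (.1,.4,.43,.07) -> mid gets the extra
  a7 <- allocate_categories(7)
  expect_equal(unname(a7), c(2L, 1L, 4L, 0L))
  expect_equal(sum(a7), 7L)
  expect_true(all(abs(a7 - 7 * c(0.30, 0.20, 0.49, 0.01)) <= 1))
})

test_that("sampled candidates obey category length and sequence rules", {
  g <- test_genome()
  cfg <- indel_config()
  set.seed(21)
  singles <- do.call(rbind, replicate(50, sample_indel(g, "single", cfg),
                                      simplify = FALSE))
  expect_true(all(singles$length == 1L))

  reps <- do.call(rbind, replicate(100, sample_indel(g, "repeat_expansion", cfg),
                                   simplify = FALSE))
  expect_true(all(reps$kind == "insertion"))
  # the inserted sequence is an integer number of tandem copies of the motif
  # immediately left of the anchor
  ok <- vapply(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    chrom_seq <- g$chromosomes[[r$chrom]]
    any(vapply(1:5, function(m) {
      r$length %% m == 0 && r$length / m >= 2 &&
        r$seq == strrep(substring(chrom_seq, r$pos - m + 1, r$pos), r$length / m)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))

  longs <- do.call(rbind, replicate(100, sample_indel(g, "long", cfg),
                                    simplify = FALSE))
  expect_true(all(longs$length >= 21 & longs$length <= 100))
  del <- longs[longs$kind == "deletion", ]
  expect_true(all(del$pos + del$length - 1 <= g$lengths[del$chrom]))
  # deletion sequences come from the reference and contain no N
  expect_identical(del$seq, unname(substring(g$chromosomes[del$chrom], del$pos,
                                             del$pos + del$length - 1)))
  expect_false(any(grepl("N", del$seq)))
})

test_that("dedup keeps first at a position, drops overlaps, trims to target", {
  two <- data.frame(chrom = "chr1", pos = c(500L, 500L), kind = "insertion",
                    length = c(3L, 5L), seq = c("AAA", "CCCCC"),
                    category = "mid")
  expect_equal(nrow(dedup_sort(two)), 1L)
  expect_equal(dedup_sort(two)$length, 3L)

  overlap <- data.frame(chrom = "chr1", pos = c(100L, 105L, 200L),
                        kind = c("deletion", "insertion", "insertion"),
                        length = c(10L, 2L, 2L), seq = c(strrep("A", 10), "GG", "TT"),
                        category = "mid")
  expect_equal(dedup_sort(overlap)$pos, c(100L, 200L))

  unique_set <- data.frame(chrom = "chr1", pos = seq(10L, 1059L * 20L, by = 20L)[1:1050],
                           kind = "insertion", length = 1L, seq = "A",
                           category = "single")
  expect_equal(nrow(dedup_sort(unique_set, n_requested = 1000)), 1000L)
  expect_equal(nrow(dedup_sort(unique_set, n_requested = Inf)), 1050L)
})

test_that("indel zygosity follows the het:hom ratio and fills both allele logs", {
  rec <- data.frame(chrom = "c", pos = 1:1000, kind = "insertion", length = 1L,
                    seq = "A", category = "single")
  set.seed(31)
  expect_true(all(assign_indel_zygosity(rec, Inf)$zygosity == "het"))
  all_hom <- assign_indel_zygosity(rec, 0)
  expect_true(all(all_hom$zygosity == "hom"))
  prefix <- tempfile()
  write_indel_logs(all_hom, prefix)
  for (k in 1:2) {
    expect_equal(nrow(utils::read.table(paste0(prefix, "_allele", k, ".tsv"),
                                        header = TRUE, sep = "\t")), 1000L)
  }
  big <- assign_indel_zygosity(rec[rep(1, 1e5), ], 1)
  expect_lt(abs(mean(big$zygosity == "het") - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("simulate_indels returns the requested count with valid records", {
  g <- test_genome()
  expect_equal(nrow(simulate_indels(g, indel_config(n_indels = 0, seed = 1))), 0L)
  ind <- simulate_indels(g, indel_config(n_indels = 2000, seed = 41))
  expect_equal(nrow(ind), 2000L)
  expect_true(all(ind$length >= 1 & ind$length <= 100))
  expect_true(all(ind$length == nchar(ind$seq)))
  # category/length consistency
  expect_true(all(ind$length[ind$category == "single"] == 1L))
  expect_true(all(ind$length[ind$category == "mid"] %in% 2:20))
  expect_true(all(ind$length[ind$category == "long"] %in% 21:100))
  expect_true(all(ind$length[ind$category == "repeat_expansion"] %in% 2:20))
  # spans unique and non-overlapping after sorting
  for (chrom in unique(ind$chrom)) {
    x <- ind[ind$chrom == chrom, ]
    x <- x[order(x$pos), ]
    ends <- x$pos + ifelse(x$kind == "deletion", x$length - 1L, 0L)
    if (nrow(x) > 1L) expect_true(all(x$pos[-1] > ends[-nrow(x)]))
  }
  # deletions never intersect N-regions
  del <- ind[ind$kind == "deletion", ]
  expect_false(any(grepl("N", del$seq)))
})

test_that("indel simulation is deterministic and rate converts to count", {
  g <- test_genome()
  a <- simulate_indels(g, indel_config(n_indels = 500, seed = 51))
  b <- simulate_indels(g, indel_config(n_indels = 500, seed = 51))
  expect_identical(a, b)
  r <- simulate_indels(g, indel_config(indel_rate = 3e-4, seed = 52))
  expect_equal(nrow(r), round(3e-4 * sum(g$lengths)))
})
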