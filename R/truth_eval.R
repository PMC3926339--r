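#' Read a variant caller's VCF into simple variant records
#'
#' Uses vcfR to parse VCF 4.x and classifies each record from REF/ALT:
#' equal single bases are SNVs; a longer REF is a deletion (position of the
#' first deleted base, length `nchar(REF) - 1`); a longer ALT is an
#' insertion (anchored at POS, inserted sequence after the shared base).
#' Multi-allelic records contribute one entry per ALT allele; symbolic and
#' complex alleles are skipped.
#'
#' @param path VCF path (plain or gzipped).
#' @return data.frame with `type` (`snv`/`indel`), `chrom`, `pos`, `ref`,
#'   `alt`, `kind`, `length`.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(type = character(0), chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), length = integer(0)))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  reps <- lengths(alts)
  chrom <- rep(fix$CHROM, reps)
  pos <- rep(as.integer(fix$POS), reps)
  ref <- rep(fix$REF, reps)
  alt <- unlist(alts)
  keep <- grepl("^[ACGTNacgtn]+$", alt) & grepl("^[ACGTNacgtn]+$", ref)
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- toupper(ref[keep]); alt <- toupper(alt[keep])
  nr <- nchar(ref); na <- nchar(alt)
  type <- ifelse(nr == 1L & na == 1L, "snv", "indel")
  kind <- ifelse(type == "snv", NA_character_,
                 ifelse(nr > na, "deletion", "insertion"))
  out_pos <- ifelse(type == "indel" & kind == "deletion", pos + 1L, pos)
  len <- ifelse(type == "snv", 1L, abs(nr - na))
  data.frame(type = type, chrom = chrom, pos = out_pos, ref = ref, alt = alt,
             kind = kind, length = as.integer(len))
}

#' Write a truth set as minimal VCF 4.2
#'
#' Left-anchored REF/ALT with a GT sample column (`0|1`/`1|0` for
#' heterozygous by allele, `1|1` for homozygous), directly comparable by
#' standard VCF tools. Deletions are re-anchored on the base before the
#' deleted span.
#'
#' @param genome The `ref_genome` the variants were simulated on.
#' @param snvs,indels Truth data.frames (either may be `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(genome, snvs = NULL, indels = NULL, path) {
  rows <- list()
  gt <- function(zyg, allele) {
    ifelse(zyg == "hom", "1|1", ifelse(allele == "1", "1|0", "0|1"))
  }
  if (!is.null(snvs) && nrow(snvs) > 0L) {
    rows[[1]] <- data.frame(chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref,
                            alt = snvs$alt, gt = gt(snvs$zygosity, snvs$allele))
  }
  if (!is.null(indels) && nrow(indels) > 0L) {
    ins <- indels$kind == "insertion"
    anchor_pos <- ifelse(ins, indels$pos, indels$pos - 1L)
    if (any(anchor_pos < 1L)) stop("deletion at position 1 cannot be left-anchored")
    anchor <- vapply(seq_len(nrow(indels)), function(i) {
      substring(genome$chromosomes[[indels$chrom[i]]], anchor_pos[i], anchor_pos[i])
    }, "")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = indels$chrom, pos = anchor_pos,
      ref = ifelse(ins, anchor, paste0(anchor, indels$seq)),
      alt = ifelse(ins, paste0(anchor, indels$seq), anchor),
      gt = gt(indels$zygosity, indels$allele))
  }
  df <- do.call(rbind, rows)
  if (!is.null(df)) {
    ci <- match(df$chrom, names(genome$chromosomes))
    df <- df[order(ci, df$pos), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", names(genome$chromosomes),
                      ",length=", unname(genome$lengths), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsim"), con)
  if (!is.null(df)) {
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".",
                     "GT", df$gt, sep = "\t"), con)
  }
  invisible(path)
}

.INDEL_BINS <- data.frame(label = c("indel_1_6", "indel_7_10", "indel_11_20",
                                    "indel_21_100"),
                          lo = c(1L, 7L, 11L, 21L), hi = c(6L, 10L, 20L, 100L))

#' Match called variants to the simulated truth set
#'
#' SNVs match on identical chromosome, position and alternate allele
#' (tolerance 0). Indels match on chromosome, kind and equal length, with
#' `|position difference| <= position_tolerance` (default 10) to absorb
#' left/right alignment ambiguity; each truth record is matched greedily to
#' the nearest unused call. Rediscovery percentages are reported per
#' stratum: SNV overall/het/hom, indel overall and size bins 1-6, 7-10,
#' 11-20, 21-100.
#'
#' @param truth_snvs SNV truth data.frame (may be `NULL`).
#' @param truth_indels Indel truth data.frame (may be `NULL`).
#' @param called Called variants: a data.frame from [read_variant_vcf()] or
#'   a VCF path.
#' @param position_tolerance Indel position tolerance in bases.
#' @return An object of class `rediscovery_report`: data.frame with
#'   `stratum`, `truth`, `matched`, `pct`, plus the tolerance used.
#' @export
match_variants <- function(truth_snvs = NULL, truth_indels = NULL, called,
                           position_tolerance = 10L) {
  if (is.character(called)) called <- read_variant_vcf(called)
  truth_chroms <- unique(c(truth_snvs$chrom, truth_indels$chrom))
  if (length(truth_chroms) > 0L && nrow(called) > 0L &&
      length(intersect(truth_chroms, unique(called$chrom))) == 0L) {
    stop("chromosome names in truth and calls do not overlap; truth has: ",
         paste(truth_chroms, collapse = ", "), "; calls have: ",
         paste(unique(called$chrom), collapse = ", "))
  }
  # SNVs: exact key match
  snv_matched <- logical(0)
  if (!is.null(truth_snvs) && nrow(truth_snvs) > 0L) {
    calls <- called[called$type == "snv", , drop = FALSE]
    snv_matched <- paste(truth_snvs$chrom, truth_snvs$pos, truth_snvs$alt) %in%
      paste(calls$chrom, calls$pos, calls$alt)
  }
  # Indels: greedy nearest-position within tolerance, per (chrom, kind, length)
  ind_matched <- logical(0)
  if (!is.null(truth_indels) && nrow(truth_indels) > 0L) {
    ind_matched <- rep(FALSE, nrow(truth_indels))
    calls <- called[called$type == "indel", , drop = FALSE]
    tkey <- paste(truth_indels$chrom, truth_indels$kind, truth_indels$length)
    ckey <- paste(calls$chrom, calls$kind, calls$length)
    for (key in unique(tkey)) {
      ti <- which(tkey == key)
      cpos <- sort(calls$pos[ckey == key])
      if (length(cpos) == 0L) next
      used <- logical(length(cpos))
      for (i in ti[order(truth_indels$pos[ti])]) {
        d <- abs(cpos - truth_indels$pos[i])
        d[used] <- Inf
        j <- which.min(d)
        if (d[j] <= position_tolerance) {
          ind_matched[i] <- TRUE
          used[j] <- TRUE
        }
      }
    }
  }
  stratum <- function(label, keep, matched) {
    data.frame(stratum = label, truth = sum(keep), matched = sum(matched & keep),
               pct = if (sum(keep) > 0L) 100 * sum(matched & keep) / sum(keep)
                     else NA_real_)
  }
  rows <- list()
  st <- if (!is.null(truth_snvs)) nrow(truth_snvs) else 0L
  zyg <- if (st > 0L) truth_snvs$zygosity else character(0)
  rows[[1]] <- stratum("snv_all", rep(TRUE, st), snv_matched)
  rows[[2]] <- stratum("snv_het", zyg == "het", snv_matched)
  rows[[3]] <- stratum("snv_hom", zyg == "hom", snv_matched)
  it <- if (!is.null(truth_indels)) nrow(truth_indels) else 0L
  rows[[4]] <- stratum("indel_all", rep(TRUE, it), ind_matched)
  for (b in seq_len(nrow(.INDEL_BINS))) {
    keep <- if (it > 0L) truth_indels$length >= .INDEL_BINS$lo[b] &
      truth_indels$length <= .INDEL_BINS$hi[b] else logical(0)
    rows[[4L + b]] <- stratum(.INDEL_BINS$label[b], keep, ind_matched)
  }
  structure(list(strata = do.call(rbind, rows),
                 position_tolerance = position_tolerance),
            class = "rediscovery_report")
}

#' @exportS3Method base::print
print.rediscovery_report <- function(x, ...) {
  cat("Variant rediscovery (indel position tolerance:",
      x$position_tolerance, "bases)\n")
  df <- x$strata
  df$pct <- ifelse(is.na(df$pct), "-", sprintf("%.1f%%", df$pct))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a rediscovery report as TSV
#'
#' @param report A `rediscovery_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rediscovery_report <- function(report, path) {
  utils::write.table(report$strata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
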