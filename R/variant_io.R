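# Variant-call and coverage I/O, the standard hard filters, and allele
# balance.

#' Construct a coverage track
#'
#' @param depth Named list (one element per scaffold) of non-negative numeric
#'   vectors: depth per position (`bin_size = 1`) or per fixed-step bin.
#' @param bin_size Bin width in bases.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(depth, bin_size = 1L) {
  stopifnot(is.list(depth), !is.null(names(depth)), bin_size >= 1)
  if (any(vapply(depth, function(d) any(d < 0), logical(1))))
    stop("depths must be non-negative")
  structure(list(depth = depth, bin_size = as.integer(bin_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$depth), "scaffold(s), bin", x$bin_size,
      "bp\n")
  invisible(x)
}

#' Rebin a coverage track to coarser bins
#'
#' @param track A `coverage_track`.
#' @param bin_size New bin size (bases), a multiple of the current one.
#' @return A `coverage_track` whose values are means over the new bins; a
#'   partial final bin averages its available positions.
#' @export
bin_track <- function(track, bin_size) {
  stopifnot(inherits(track, "coverage_track"))
  if (bin_size == track$bin_size) return(track)
  if (bin_size %% track$bin_size != 0)
    stop("new bin size must be a multiple of the current bin size")
  fold <- bin_size %/% track$bin_size
  depth <- lapply(track$depth, function(d) {
    grp <- (seq_along(d) - 1L) %/% fold
    as.numeric(tapply(d, grp, mean))
  })
  coverage_track(depth, bin_size)
}

#' Write a depth track as TSV
#'
#' Columns: scaffold, pos (1-based start of the bin), depth.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  rows <- lapply(names(track$depth), function(s) {
    d <- track$depth[[s]]
    data.frame(scaffold = s,
               pos = (seq_along(d) - 1L) * track$bin_size + 1L,
               depth = d)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth track from TSV
#'
#' @param path TSV with columns scaffold, pos, depth, as written by
#'   [write_depth_tsv()].
#' @return A `coverage_track` (bin size inferred from the position step).
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "pos", "depth") %in% names(df)))
  scafs <- unique(df$scaffold)
  first <- df[df$scaffold == scafs[1L], "pos"]
  bin <- if (length(first) > 1L) first[2L] - first[1L] else 1L
  depth <- lapply(scafs, function(s) df$depth[df$scaffold == s])
  names(depth) <- scafs
  coverage_track(depth, bin)
}

#' Write variant calls to VCF 4.2
#'
#' Single-sample VCF with GT, DP and AD; used for fixtures and round-trip
#' checks.
#'
#' @param records Variant-call data.frame (`scaffold`, `pos`, `ref`, `alt`,
#'   `genotype`, `depth`, `alt_depth`, `qual`).
#' @param path Output path.
#' @param sample Sample name.
#' @param seqlengths Named vector of scaffold lengths for the contig header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = "sample", seqlengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridscan",
    if (!is.null(seqlengths))
      sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
              as.integer(seqlengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[records$genotype]
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.2f\t.\t.\tGT:DP:AD\t%s:%d:%d,%d",
    records$scaffold, records$pos, records$ref, records$alt,
    records$qual, gt, records$depth,
    records$depth - records$alt_depth, records$alt_depth
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read biallelic SNP calls from a VCF
#'
#' One record per biallelic SNP; indels and multiallelic records are skipped
#' and counted. Genotype class is taken from GT (diploid-style calls, as a
#' standard caller run with ploidy 2 would emit), depth from DP and the
#' alternate read count from AD.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Variant-call data.frame with attribute `skipped` giving the count
#'   of non-SNP/multiallelic/incomplete records.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  g <- VariantAnnotation::geno(vcf)
  if (!all(c("GT", "DP", "AD") %in% names(g)))
    stop("VCF must carry GT, DP and AD genotype fields: ", path)
  if (ncol(vcf) != 1L)
    stop("expected a single-sample VCF: ", path)

  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(rr))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  gt <- as.character(g$GT[, 1L])
  dp <- as.integer(g$DP[, 1L])
  ad <- g$AD[, 1L]
  ad_len <- S4Vectors::elementNROWS(ad)

  snp <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  complete <- !is.na(gt) & gt != "./." & !is.na(dp) & ad_len == 2L &
    !is.na(as.numeric(rr$QUAL))
  keep <- snp & complete
  skipped <- sum(!keep)

  gt_class <- rep(NA_character_, length(gt))
  gt_norm <- gsub("\\|", "/", gt)
  gt_class[gt_norm %in% c("0/0")] <- "hom_ref"
  gt_class[gt_norm %in% c("0/1", "1/0")] <- "het"
  gt_class[gt_norm %in% c("1/1")] <- "hom_alt"
  keep <- keep & !is.na(gt_class)
  skipped <- sum(!snp | !complete | is.na(gt_class))

  ad2 <- vapply(ad[keep], function(x) as.integer(x[2L]), integer(1))
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt1[keep],
    genotype = gt_class[keep],
    depth = dp[keep], alt_depth = ad2,
    qual = as.numeric(rr$QUAL)[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Hard-filter variant calls on depth and quality
#'
#' Removes calls with coverage below `min_depth` or quality below `min_qual`
#' (strict inequalities: boundary values are kept), matching the standard
#' `coverage < 10x or QUAL < 25` filter applied before population analysis.
#'
#' @param records Variant-call data.frame.
#' @param min_depth Minimum depth retained.
#' @param min_qual Minimum QUAL retained.
#' @return The retained records (attribute `removed` counts the rest).
#' @export
filter_calls <- function(records, min_depth = 10, min_qual = 25) {
  keep <- records$depth >= min_depth & records$qual >= min_qual
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Allele balance of variant calls
#'
#' The fraction of reads supporting the alternate allele, `alt_depth/depth`.
#' At a true heterozygous site its expectation is (copies carrying the
#' alternate allele) / (total copies), which is what makes it informative
#' about ploidy and subgenome configuration.
#'
#' @param records Variant-call data.frame (or any data.frame with `depth`
#'   and `alt_depth`).
#' @return Numeric vector in \[0, 1\]; `NA` with a classed warning
#'   (`hybridscan_undefined`) for zero-depth records.
#' @export
allele_balance <- function(records) {
  d <- records$depth
  ab <- records$alt_depth / d
  if (any(d == 0)) {
    warning(warningCondition(
      sprintf("%d record(s) with zero depth: allele balance undefined",
              sum(d == 0)),
      class = "hybridscan_undefined"))
    ab[d == 0] <- NA_real_
  }
  ab
}

#' Mean depth in non-overlapping windows
#'
#' Tiles each scaffold from its start with fixed windows; a final partial
#' window is kept and flagged.
#'
#' @param track A `coverage_track`.
#' @param window Window size in bases (multiple of the track's bin size).
#' @return data.frame with `scaffold`, `start`, `end` (1-based inclusive),
#'   `mean_depth`, `partial`.
#' @export
coverage_windows <- function(track, window) {
  stopifnot(inherits(track, "coverage_track"), window > 0)
  if (window %% track$bin_size != 0)
    stop("window must be a multiple of the track bin size")
  per_win <- window %/% track$bin_size
  out <- lapply(names(track$depth), function(s) {
    d <- track$depth[[s]]
    grp <- (seq_along(d) - 1L) %/% per_win
    m <- as.numeric(tapply(d, grp, mean))
    n <- as.integer(tapply(d, grp, length))
    starts <- (unique(grp)) * window + 1L
    ends <- pmin(starts + window - 1L,
                 length(d) * track$bin_size)
    data.frame(scaffold = s, start = starts, end = ends,
               mean_depth = m, partial = n < per_win)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
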