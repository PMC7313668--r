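# Loss-of-heterozygosity detection: a 50-kb sliding-window scan (25-kb step)
# flags windows with at most `max_het` heterozygous sites; flagged windows
# merge into maximal regions. Because a 25-kb step quantises region ends to
# the window grid (biasing the recovered extent low by roughly half a step
# per edge), merged regions are by default refined outward to the nearest
# flanking heterozygous site, i.e. to the maximal het-free interval around
# the detected desert.

as_seqlengths <- function(genome) {
  if (inherits(genome, "ref_genome")) scaffold_lengths(genome)
  else if (is.numeric(genome) && !is.null(names(genome))) genome
  else stop("`genome` must be a ref_genome or a named length vector")
}

#' Per-scaffold heterozygous positions from variant records
#'
#' @param records Variant-call data.frame.
#' @return Named list of sorted integer positions of het calls.
#' @export
het_positions <- function(records) {
  het <- records[records$genotype == "het", , drop = FALSE]
  lapply(split(het$pos, het$scaffold), sort)
}

#' Scan a genome for LOH regions
#'
#' @param positions Named list (per scaffold) of sorted heterozygous-site
#'   positions, e.g. from [het_positions()]. Scaffolds absent from the list
#'   are treated as having no het sites.
#' @param genome A `ref_genome` or named vector of scaffold lengths.
#' @param window Window size in bases.
#' @param step Step between window starts.
#' @param max_het Maximum heterozygous sites for a window to be flagged; for
#'   the partial windows at a scaffold end the threshold is prorated by the
#'   covered fraction and rounded down.
#' @param refine_boundaries If `TRUE` (default), extend each merged region
#'   outward to the nearest flanking heterozygous sites, removing the
#'   window-grid quantisation of region ends. `FALSE` reproduces the raw
#'   union of flagged windows.
#' @return [GenomicRanges::GRanges] of disjoint LOH regions with metadata
#'   `n_windows_merged` and `het_sites_inside`.
#' @export
scan_loh <- function(positions, genome, window = 50000L, step = 25000L,
                     max_het = 10L, refine_boundaries = TRUE) {
  stopifnot(window > 0, step > 0, max_het >= 0)
  lens <- as_seqlengths(genome)
  out <- list()
  for (s in names(lens)) {
    L <- lens[[s]]
    pos <- positions[[s]] %||% integer(0)
    starts <- seq.int(1L, max(L - as.integer(window) + 1L, 1L), by = step)
    # partial windows at the scaffold end, one per remaining step
    tail_starts <- if (max(starts) + step <= L)
      seq.int(max(starts) + step, L, by = step) else integer(0)
    all_starts <- c(starts, tail_starts)
    ends <- pmin(all_starts + window - 1L, L)
    counts <- findInterval(ends, pos) - findInterval(all_starts - 1L, pos)
    thr <- floor(max_het * (ends - all_starts + 1) / window)
    flagged <- counts <= thr
    if (!any(flagged)) next
    ir <- IRanges::reduce(IRanges::IRanges(all_starts[flagged],
                                           ends[flagged]),
                          min.gapwidth = 1L,
                          with.revmap = TRUE)
    n_merged <- S4Vectors::elementNROWS(S4Vectors::mcols(ir)$revmap)
    st <- IRanges::start(ir); en <- IRanges::end(ir)
    if (refine_boundaries) {
      for (k in seq_along(st)) {
        below <- pos[pos < st[k]]
        st[k] <- if (length(below)) max(below) + 1L else 1L
        above <- pos[pos > en[k]]
        en[k] <- if (length(above)) min(above) - 1L else L
      }
      ir2 <- IRanges::reduce(IRanges::IRanges(st, en), min.gapwidth = 1L,
                             with.revmap = TRUE)
      n_merged <- vapply(S4Vectors::mcols(ir2)$revmap, function(i) sum(n_merged[i]),
                         integer(1))
      st <- IRanges::start(ir2); en <- IRanges::end(ir2)
    }
    gr <- GenomicRanges::GRanges(s, IRanges::IRanges(st, en))
    gr$n_windows_merged <- n_merged
    gr$het_sites_inside <- vapply(seq_along(gr), function(k) {
      sum(pos >= st[k] & pos <= en[k])
    }, integer(1))
    out[[s]] <- gr
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(seqlengths = lens)
    gr$n_windows_merged <- integer(0)
    gr$het_sites_inside <- integer(0)
    return(gr)
  }
  gr <- suppressWarnings(do.call(c, unname(out)))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- lens
  GenomicRanges::sort(gr)
}

#' Heterozygosity rate excluding LOH regions
#'
#' Heterozygous SNPs inside LOH are discarded and the LOH bases are
#' subtracted from the genome length, giving the rate per kb of the
#' heterozygous genome fraction.
#'
#' @param positions Named list of sorted het positions per scaffold.
#' @param loh [GenomicRanges::GRanges] of LOH regions (disjoint).
#' @param genome A `ref_genome` or named length vector.
#' @return Heterozygous sites per kb outside LOH.
#' @export
heterozygosity_excluding_loh <- function(positions, loh, genome) {
  lens <- as_seqlengths(genome)
  total <- sum(as.numeric(lens))
  loh <- GenomicRanges::reduce(loh)
  loh_len <- sum(as.numeric(GenomicRanges::width(loh)))
  if (total - loh_len <= 0)
    undefined_error("LOH covers the entire genome: rate undefined")
  n_out <- 0L
  for (s in names(positions)) {
    pos <- positions[[s]]
    loh_s <- loh[GenomicRanges::seqnames(loh) == s]
    if (length(loh_s)) {
      inside <- IRanges::overlapsAny(
        IRanges::IRanges(pos, pos), IRanges::ranges(loh_s))
      n_out <- n_out + sum(!inside)
    } else n_out <- n_out + length(pos)
  }
  n_out / ((total - loh_len) / 1000)
}

#' Fraction of the genome covered by LOH
#'
#' @param loh [GenomicRanges::GRanges] of LOH regions.
#' @param genome A `ref_genome` or named length vector.
#' @return Merged LOH length / genome length.
#' @export
loh_genome_fraction <- function(loh, genome) {
  lens <- as_seqlengths(genome)
  loh <- GenomicRanges::reduce(loh)
  sum(as.numeric(GenomicRanges::width(loh))) / sum(as.numeric(lens))
}
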