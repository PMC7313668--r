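# Read-depth copy-number analysis: median-normalised window ratios, a
# transparent rounding-based segmenter (window 1 kb, step 200 bp, 6-kb
# telomere/centromere edge exclusion -- the parameters of the standard
# depth-ratio CNV callers), whole-scaffold aneuploidy calls, gene-level copy
# numbers via the >50%-overlap rule, triploid subgenome attribution of
# segmental events from allele-balance shifts, and core/accessory
# classification of the gene set.

#' Median-normalised depth ratios in sliding windows
#'
#' Window means divided by the genome-wide median window depth. Windows
#' within `edge_exclusion` bases of a scaffold end are flagged `excluded`
#' and ignored by the segmenter (depth there is unreliable at telomeres and
#' centromeres).
#'
#' @param track A `coverage_track` (per-position, or binned so that the bin
#'   divides both `window` and `step`).
#' @param window Window size in bases.
#' @param step Step between window starts in bases.
#' @param edge_exclusion Bases excluded at each scaffold end.
#' @return data.frame: `scaffold`, `start`, `end`, `center`, `mean_depth`,
#'   `ratio`, `excluded`.
#' @export
normalize_ratios <- function(track, window = 1000L, step = 200L,
                             edge_exclusion = 6000L) {
  stopifnot(inherits(track, "coverage_track"), window > 0, step > 0,
            edge_exclusion >= 0)
  bin <- track$bin_size
  if (window %% bin != 0 || step %% bin != 0)
    stop("window and step must be multiples of the track bin size")
  wb <- window %/% bin; sb <- step %/% bin
  out <- lapply(names(track$depth), function(s) {
    d <- track$depth[[s]]
    L <- length(d) * bin
    if (L < 2 * edge_exclusion + window)
      stop("scaffold ", s, " shorter than twice the edge exclusion")
    cs <- c(0, cumsum(as.numeric(d)))
    first <- seq.int(1L, length(d) - wb + 1L, by = sb)
    m <- (cs[first + wb] - cs[first]) / wb
    start <- (first - 1L) * bin + 1L
    end <- start + window - 1L
    data.frame(scaffold = s, start = start, end = end,
               center = (start + end) / 2, mean_depth = m,
               excluded = start <= edge_exclusion | end > L - edge_exclusion)
  })
  df <- do.call(rbind, out)
  med <- stats::median(df$mean_depth)
  if (med <= 0) stop("genome-wide median window depth is zero")
  df$ratio <- df$mean_depth / med
  rownames(df) <- NULL
  df
}

#' Segment window depth ratios into copy-number segments
#'
#' Per-window copy number is `round(ratio * ploidy)`; runs of equal CN merge
#' into segments whose boundaries fall midway between the flanking window
#' centers; segments spanning less than `min_span` bases are absorbed into
#' their longer flank (the analog of a break-point penalty), and equal-CN
#' neighbours re-merge until stable. Segments tile each scaffold's
#' non-excluded span exactly.
#'
#' @param ratios data.frame from [normalize_ratios()].
#' @param ploidy Isolate base ploidy.
#' @param min_span Minimum segment span in bases.
#' @return [GenomicRanges::GRanges] with `copy_number`, `klass`
#'   (gain/loss/neutral) and `mean_ratio`.
#' @export
segment_cn <- function(ratios, ploidy, min_span = 10000L) {
  stopifnot(ploidy >= 1, min_span >= 0)
  segs <- list()
  for (s in unique(ratios$scaffold)) {
    w <- ratios[ratios$scaffold == s & !ratios$excluded, , drop = FALSE]
    if (!nrow(w)) next
    w <- w[order(w$start), , drop = FALSE]
    cn <- as.integer(round(w$ratio * ploidy))
    # boundaries between consecutive windows: midpoint of centers
    cuts <- floor((w$center[-nrow(w)] + w$center[-1L]) / 2)
    span_lo <- c(w$start[1L], cuts + 1)
    span_hi <- c(cuts, w$end[nrow(w)])

    r <- rle(cn)
    runs <- data.frame(
      from = cumsum(c(1L, r$lengths[-length(r$lengths)])),
      to = cumsum(r$lengths), cn = r$values
    )
    run_span <- function(runs) {
      span_hi[runs$to] - span_lo[runs$from] + 1
    }
    repeat {
      sp <- run_span(runs)
      short <- which(sp < min_span)
      if (!length(short) || nrow(runs) == 1L) break
      k <- short[which.min(sp[short])]
      nb <- c(k - 1L, k + 1L)
      nb <- nb[nb >= 1L & nb <= nrow(runs)]
      takeover <- nb[which.max(sp[nb])]
      runs$cn[k] <- runs$cn[takeover]
      # merge equal adjacent runs
      keep <- c(TRUE, runs$cn[-1L] != runs$cn[-nrow(runs)])
      grp <- cumsum(keep)
      runs <- data.frame(
        from = tapply(runs$from, grp, min),
        to = tapply(runs$to, grp, max),
        cn = tapply(runs$cn, grp, function(x) x[1L])
      )
    }
    sp_lo <- span_lo[runs$from]; sp_hi <- span_hi[runs$to]
    mr <- vapply(seq_len(nrow(runs)), function(k) {
      mean(w$ratio[runs$from[k]:runs$to[k]])
    }, numeric(1))
    gr <- GenomicRanges::GRanges(s, IRanges::IRanges(sp_lo, sp_hi))
    gr$copy_number <- as.integer(runs$cn)
    gr$klass <- ifelse(runs$cn > ploidy, "gain",
                       ifelse(runs$cn < ploidy, "loss", "neutral"))
    gr$mean_ratio <- mr
    segs[[s]] <- gr
  }
  if (!length(segs)) {
    gr <- GenomicRanges::GRanges()
    gr$copy_number <- integer(0); gr$klass <- character(0)
    gr$mean_ratio <- numeric(0)
    return(gr)
  }
  suppressWarnings(GenomicRanges::sort(do.call(c, unname(segs))))
}

#' Whole-scaffold aneuploidy calls from coarse window means
#'
#' A scaffold is called gained (lost) when at least `consistency` of its
#' 20-kb windows round to a copy number above (below) the base ploidy; a
#' reproducible surrogate for calling aneuploidies off a coverage plot.
#'
#' @param windows data.frame from [coverage_windows()] (typically 20-kb).
#' @param ploidy Base ploidy.
#' @param min_windows Minimum windows per scaffold to attempt a call.
#' @param consistency Fraction of windows that must deviate consistently.
#' @return data.frame: `scaffold`, `call` (euploid/gained/lost),
#'   `copy_number` (modal CN), `frac_deviant`.
#' @export
detect_aneuploidy <- function(windows, ploidy, min_windows = 5L,
                              consistency = 0.9) {
  med <- stats::median(windows$mean_depth)
  if (med <= 0) stop("median window depth is zero")
  cn <- as.integer(round(windows$mean_depth / med * ploidy))
  out <- lapply(split(seq_len(nrow(windows)), windows$scaffold), function(i) {
    scf <- windows$scaffold[i[1L]]
    if (length(i) < min_windows) {
      return(data.frame(scaffold = scf, call = "euploid",
                        copy_number = ploidy, frac_deviant = NA_real_))
    }
    ci <- cn[i]
    up <- mean(ci > ploidy); down <- mean(ci < ploidy)
    call <- if (up >= consistency) "gained"
            else if (down >= consistency) "lost" else "euploid"
    modal <- as.integer(names(sort(table(ci), decreasing = TRUE))[1L])
    data.frame(scaffold = scf, call = call,
               copy_number = if (call == "euploid") ploidy else modal,
               frac_deviant = max(up, down))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Gene-level copy number from CNV segments
#'
#' A gene takes the copy number of the segment class covering more than half
#' of its length; genes with no class past one half (including genes mostly
#' outside the segmented span, e.g. in the edge-excluded zones) keep the base
#' ploidy and are flagged.
#'
#' @param segments [GenomicRanges::GRanges] from [segment_cn()].
#' @param genes [GenomicRanges::GRanges] with `gene_id`.
#' @param ploidy Base ploidy.
#' @return data.frame: `gene_id`, `copy_number`, `klass`,
#'   `covered_fraction` (fraction of the gene inside the assigned class).
#' @export
gene_copy_number <- function(segments, genes, ploidy) {
  n <- length(genes)
  cn <- rep(as.integer(ploidy), n)
  frac <- numeric(n)
  if (length(segments)) {
    hits <- GenomicRanges::findOverlaps(genes, segments,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); sub <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::pintersect(GenomicRanges::granges(genes)[q],
                                      GenomicRanges::granges(segments)[sub],
                                      ignore.strand = TRUE)
      ovw <- GenomicRanges::width(ov)
      key <- paste(q, segments$copy_number[sub])
      agg <- tapply(ovw, key, sum)
      kq <- as.integer(sub("\\s.*", "", names(agg)))
      kcn <- as.integer(sub(".*\\s", "", names(agg)))
      gw <- GenomicRanges::width(genes)
      for (g in unique(kq)) {
        i <- kq == g
        best <- which.max(agg[i])
        f <- agg[i][best] / gw[g]
        if (f > 0.5) {
          cn[g] <- kcn[i][best]
          frac[g] <- f
        }
      }
    }
  }
  data.frame(
    gene_id = genes$gene_id, copy_number = cn,
    klass = ifelse(cn > ploidy, "duplicated",
                   ifelse(cn < ploidy, "lost", "unchanged")),
    covered_fraction = frac
  )
}

# copy multiplicities (D1, D2, H) of a triploid after each structural
# configuration; templates derive from these, never from literals
.triploid_configurations <- list(
  gain = list(
    "3:1" = c(D1 = 2L, D2 = 1L, H = 1L),  # extra copy of the diploid version
    "2:2" = c(D1 = 1L, D2 = 1L, H = 2L)   # duplication of the haploid version
  ),
  loss = list(
    "2:0" = c(D1 = 1L, D2 = 1L, H = 0L),  # haploid version deleted
    "1:1" = c(D1 = 1L, D2 = 0L, H = 1L)   # one diploid copy deleted
  )
)

#' Expected allele-balance templates of triploid subgenome configurations
#'
#' For each copy configuration of an allotriploid segment, the expected
#' alternate-allele fractions at subgenome-distinguishing heterozygous sites
#' (alternate allele on the haploid version, or shared by both diploid
#' copies), computed from the copy counts. A supplemental diploid copy (3:1)
#' gives 0.25 and 0.75; a duplicated haploid version (2:2) gives 0.5;
#' deleting the haploid version (2:0) leaves balance 1; deleting one diploid
#' copy (1:1) gives 0.5.
#'
#' @param klass `"gain"` or `"loss"`.
#' @return Named list of numeric mode vectors, one per configuration.
#' @export
subgenome_templates <- function(klass = c("gain", "loss")) {
  klass <- match.arg(klass)
  lapply(.triploid_configurations[[klass]], function(mult) {
    total <- sum(mult)
    modes <- c(
      haploid_alt = unname(mult["H"]) / total,          # alt on H
      diploid_alt = unname(mult["D1"] + mult["D2"]) / total  # alt on D1+D2
    )
    # a deleted carrier contributes no observable site; drop zero modes and
    # collapse coinciding ones
    sort(unique(modes[modes > 0]))
  })
}

#' Attribute a triploid CNV segment to a subgenome configuration
#'
#' Decides which genome version a segmental gain or loss affected, from the
#' allele balances of the variant calls inside the segment. The
#' configuration templates ([subgenome_templates()]) share their lower modes
#' once the diploid subgenome's own heterozygous sites are accounted for
#' (e.g. a 2:2 segment also shows sites near 0.25, and a 1:1 segment is
#' unimodal at the 0.5 mode that 2:0 retains for surviving heterozygosity),
#' so the decisive signal is the template mode unique to one configuration:
#' 0.75 for gains (supplemental diploid copy, 3:1) and 1.0 for losses
#' (haploid version deleted, 2:0). The segment is attributed to that
#' configuration when at least `high_frac` of balances fall within 0.125 of
#' the discriminative mode, to the alternative when at most `low_frac` do,
#' and left unresolved in between or when fewer than `min_sites` balances
#' are available.
#'
#' @param klass `"gain"` or `"loss"`.
#' @param balances Allele balances of the variant calls inside the segment
#'   (heterozygous and homozygous-alternate: formerly heterozygous sites
#'   driven to balance 1 by a haploid-version loss surface as hom_alt).
#' @param min_sites Minimum number of sites.
#' @param high_frac,low_frac Decision thresholds on the fraction of sites at
#'   the discriminative mode.
#' @return List with `configuration` (`"3:1"`, `"2:2"`, `"2:0"`, `"1:1"` or
#'   `"unresolved"`), `disc_mode`, `disc_frac`, `n_sites`, `reason`.
#' @export
subgenome_attribution <- function(klass, balances, min_sites = 20L,
                                  high_frac = 0.2, low_frac = 0.1) {
  klass <- match.arg(klass, c("gain", "loss"))
  balances <- balances[!is.na(balances)]
  tmpl <- subgenome_templates(klass)
  # the mode present in exactly one configuration's template
  modes <- unlist(tmpl)
  tab <- table(modes)
  disc <- max(as.numeric(names(tab)[tab == 1L]))
  disc_cfg <- names(tmpl)[vapply(tmpl, function(m) disc %in% m, logical(1))]
  other_cfg <- setdiff(names(tmpl), disc_cfg)
  if (length(balances) < min_sites) {
    return(list(configuration = "unresolved", disc_mode = disc,
                disc_frac = NA_real_, n_sites = length(balances),
                reason = sprintf("only %d informative sites (minimum %d)",
                                 length(balances), min_sites)))
  }
  frac <- mean(abs(balances - disc) <= 0.125)
  cfg <- if (frac >= high_frac) disc_cfg
         else if (frac <= low_frac) other_cfg
         else "unresolved"
  list(configuration = cfg, disc_mode = disc, disc_frac = frac,
       n_sites = length(balances),
       reason = if (cfg == "unresolved")
         "discriminative-mode mass between thresholds" else NA_character_)
}

#' Assemble a gene-by-isolate copy-number matrix
#'
#' @param gene_cn_list Named list (per isolate) of [gene_copy_number()]
#'   outputs.
#' @return Integer matrix, genes x isolates.
#' @export
gene_cn_matrix <- function(gene_cn_list) {
  stopifnot(length(gene_cn_list) >= 1L)
  ids <- gene_cn_list[[1L]]$gene_id
  m <- vapply(gene_cn_list, function(df) {
    stopifnot(identical(df$gene_id, ids))
    as.integer(df$copy_number)
  }, integer(length(ids)))
  rownames(m) <- ids
  m
}

#' Core/accessory classification of the gene set
#'
#' A gene is core when present (copy number >= 1) in every isolate and
#' accessory otherwise.
#'
#' @param cn_matrix Integer gene x isolate matrix, e.g. [gene_cn_matrix()].
#' @return List with `core`, `accessory` (counts), `classes` (per-gene
#'   data.frame) and `presence` (logical matrix).
#' @export
core_accessory <- function(cn_matrix) {
  stopifnot(is.matrix(cn_matrix), all(cn_matrix >= 0))
  presence <- cn_matrix >= 1L
  core <- rowSums(presence) == ncol(cn_matrix)
  list(
    core = sum(core), accessory = sum(!core),
    classes = data.frame(gene_id = rownames(cn_matrix),
                         class = unname(ifelse(core, "core", "accessory"))),
    presence = presence
  )
}
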