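# Windowed nucleotide-diversity statistics on IUPAC-encoded cohort
# alignments. Each isolate contributes ONE sequence in which heterozygous
# sites are ambiguity codes; comparisons involving ambiguity codes use the
# expected mismatch under equal-probability resolution of each code
# (contribution 1 - sum_b p1(b) p2(b)). pi, Watterson's theta and Tajima's D
# follow the standard definitions with that expected-mismatch kernel.

#' Build the sparse IUPAC alignment of a cohort
#'
#' Collects every position at which any isolate carries a variant and encodes
#' each isolate's state there: reference base for absent/hom_ref calls, the
#' alternate base for hom_alt, the two-base ambiguity code for het. Positions
#' absent from an isolate's records are treated as reference (fixture VCFs
#' are exhaustive; with real data this assumption is the caller's to check).
#'
#' @param records_list Named list (one element per isolate) of variant-call
#'   data.frames sharing the reference coordinate space.
#' @param ref A `ref_genome` (supplies reference bases and lengths).
#' @return An `iupac_alignment`: list with `codes` (character matrix,
#'   variant positions x isolates), `scaffold`, `pos`, `isolates`,
#'   `seqlengths`.
#' @export
snp_alignment <- function(records_list, ref) {
  stopifnot(is.list(records_list), !is.null(names(records_list)))
  lens <- as_seqlengths(ref)
  isolates <- names(records_list)
  all_sites <- unique(do.call(rbind, lapply(records_list, function(r)
    r[c("scaffold", "pos", "ref")])))
  o <- order(match(all_sites$scaffold, names(lens)), all_sites$pos)
  all_sites <- all_sites[o, , drop = FALSE]
  if (anyDuplicated(paste(all_sites$scaffold, all_sites$pos)))
    stop("conflicting reference alleles at a shared position")
  key <- paste(all_sites$scaffold, all_sites$pos)
  codes <- matrix(all_sites$ref, nrow = nrow(all_sites),
                  ncol = length(isolates),
                  dimnames = list(NULL, isolates))
  for (iso in isolates) {
    r <- records_list[[iso]]
    if (!nrow(r)) next
    rkey <- paste(r$scaffold, r$pos)
    if (anyDuplicated(rkey)) {
      dup <- rkey[duplicated(rkey)][1L]
      stop("conflicting records in isolate ", iso, " at ", dup)
    }
    idx <- match(rkey, key)
    enc <- character(nrow(r))
    enc[r$genotype == "hom_ref"] <- r$ref[r$genotype == "hom_ref"]
    enc[r$genotype == "hom_alt"] <- r$alt[r$genotype == "hom_alt"]
    het <- r$genotype == "het"
    if (any(het)) enc[het] <- iupac_het_code(r$ref[het], r$alt[het])
    codes[idx, iso] <- enc
  }
  structure(list(codes = codes, scaffold = all_sites$scaffold,
                 pos = all_sites$pos, isolates = isolates,
                 seqlengths = lens),
            class = "iupac_alignment")
}

#' @export
print.iupac_alignment <- function(x, ...) {
  cat("iupac_alignment:", length(x$isolates), "isolates,",
      nrow(x$codes), "variant columns\n")
  invisible(x)
}

#' Full-length IUPAC consensus sequences per isolate
#'
#' Materialises each isolate's concatenated-genome sequence: the reference
#' with hom_alt substitutions applied and het sites as ambiguity codes.
#' Intended for small genomes and for export; all statistics work on the
#' sparse [snp_alignment()] directly.
#'
#' @inheritParams snp_alignment
#' @return Named character vector, one concatenated sequence per isolate.
#' @export
build_alignment <- function(records_list, ref) {
  stopifnot(inherits(ref, "ref_genome"))
  aln <- snp_alignment(records_list, ref)
  lens <- scaffold_lengths(ref)
  offsets <- cumsum(c(0, as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)
  refseq <- strsplit(paste(as.character(ref$scaffolds), collapse = ""),
                     "")[[1]]
  gpos <- offsets[aln$scaffold] + aln$pos
  out <- vapply(aln$isolates, function(iso) {
    s <- refseq
    s[gpos] <- aln$codes[, iso]
    paste(s, collapse = "")
  }, character(1))
  attr(out, "scaffold_offsets") <- offsets
  out
}

# rows x 2 summary of a code matrix: total expected pairwise mismatch per
# row, and whether the row is segregating (more than one distinct code)
.pair_mismatch_rows <- function(codes) {
  n <- ncol(codes)
  idx <- matrix(iupac_index(codes), nrow = nrow(codes))
  sumsq <- 0
  for (b in 1:4) {
    pb <- matrix(.iupac_prob[, b][idx], nrow = nrow(codes))
    sumsq <- sumsq + rowSums(pb)^2
  }
  selfsq <- rowSums(.iupac_prob^2)
  qsum <- rowSums(matrix(selfsq[idx], nrow = nrow(codes)))
  mism <- choose(n, 2) - (sumsq - qsum) / 2
  seg <- vapply(seq_len(nrow(codes)), function(i) {
    length(unique(codes[i, ])) > 1L
  }, logical(1))
  cbind(mismatch = mism, segregating = seg)
}

# accept either an iupac_alignment or a character vector of equal-length
# sequences; returns list(codes matrix, L = per-site denominator)
.as_code_matrix <- function(x) {
  if (inherits(x, "iupac_alignment")) {
    list(codes = x$codes, L = sum(as.numeric(x$seqlengths)))
  } else if (is.character(x)) {
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("sequences must have equal length")
    list(codes = do.call(cbind, strsplit(toupper(x), "")), L = w)
  } else stop("expected an iupac_alignment or character sequences")
}

#' Average pairwise nucleotide diversity (pi)
#'
#' Mean over all sequence pairs of the per-site expected mismatch, divided
#' by the sequence length. Invariant columns contribute zero, so the sparse
#' alignment representation is exact.
#'
#' @param x An `iupac_alignment` or character vector of aligned sequences.
#' @return pi per site.
#' @export
pairwise_pi <- function(x) {
  cm <- .as_code_matrix(x)
  n <- ncol(cm$codes)
  if (n < 2L) undefined_error("pi requires at least 2 sequences")
  if (!nrow(cm$codes)) return(0)
  pm <- .pair_mismatch_rows(cm$codes)
  sum(pm[, "mismatch"]) / choose(n, 2) / cm$L
}

#' Watterson's theta per site
#'
#' `S / (a1 * L)` with `a1` the (n-1)-th harmonic number.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @param L Sequence length in bases.
#' @return theta_w per site.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, L > 0)
  if (n < 2L) undefined_error("theta_w requires n >= 2")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

#' Tajima's D
#'
#' Standard normalised difference between the pairwise estimate of theta
#' (mean pairwise differences) and the segregating-sites estimate, with the
#' canonical variance constants in terms of n.
#'
#' @param S Segregating sites in the window.
#' @param n Number of sequences.
#' @param pi_total Mean pairwise differences in the window (a count, not per
#'   site).
#' @return D; signals a classed error (`hybridscan_undefined`) when S = 0.
#' @export
tajimas_d <- function(S, n, pi_total) {
  stopifnot(n >= 2)
  if (S == 0) undefined_error("Tajima's D undefined for S = 0")
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Partition genome positions into coding and noncoding
#'
#' Overlapping genes are unioned; every position belongs to exactly one
#' class.
#'
#' @param genes [GenomicRanges::GRanges] of gene models.
#' @param genome A `ref_genome` or named length vector.
#' @return List of two disjoint [GenomicRanges::GRanges] masks, `coding` and
#'   `noncoding`, covering the genome exactly.
#' @export
partition_sites <- function(genes, genome) {
  lens <- as_seqlengths(genome)
  all <- GenomicRanges::GRanges(names(lens),
                                IRanges::IRanges(1L, as.integer(lens)),
                                seqlengths = lens)
  coding <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                  ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(coding) <- names(lens)
  GenomeInfoDb::seqlengths(coding) <- lens
  if (any(GenomicRanges::start(coding) < 1) ||
      any(GenomicRanges::end(coding) > lens[as.character(
        GenomicRanges::seqnames(coding))]))
    stop("gene intervals outside genome bounds")
  noncoding <- GenomicRanges::setdiff(all, coding, ignore.strand = TRUE)
  list(coding = coding, noncoding = noncoding)
}

#' Windowed diversity statistics
#'
#' Tiles each scaffold with nonoverlapping windows and reports, per window,
#' the number of segregating sites S, pi, Watterson's theta and Tajima's D
#' (NA where S = 0). With a `mask`, columns and the per-site denominator are
#' restricted to masked positions (e.g. coding or noncoding).
#'
#' @param aln An `iupac_alignment`.
#' @param window Window size in bases.
#' @param mask Optional [GenomicRanges::GRanges] restricting the analysis.
#' @param isolates Optional subset of isolate names (e.g. one cluster).
#' @return data.frame with one row per window: `scaffold`, `start`, `end`,
#'   `L` (effective masked length), `n`, `S`, `pi`, `theta_w`, `tajima_d`.
#' @export
window_scan <- function(aln, window = 10000L, mask = NULL, isolates = NULL) {
  stopifnot(inherits(aln, "iupac_alignment"), window > 0)
  codes <- aln$codes
  if (!is.null(isolates)) {
    if (!all(isolates %in% aln$isolates)) stop("unknown isolate in subset")
    codes <- codes[, isolates, drop = FALSE]
  }
  n <- ncol(codes)
  if (n < 2L) undefined_error("window_scan requires >= 2 isolates")
  use <- rep(TRUE, nrow(codes))
  if (!is.null(mask)) {
    gr <- GenomicRanges::GRanges(aln$scaffold,
                                 IRanges::IRanges(aln$pos, aln$pos))
    use <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
  }
  pm <- matrix(numeric(0), 0, 2,
               dimnames = list(NULL, c("mismatch", "segregating")))
  if (any(use)) pm <- .pair_mismatch_rows(codes[use, , drop = FALSE])
  scf_use <- aln$scaffold[use]
  pos_use <- aln$pos[use]

  out <- list()
  for (s in names(aln$seqlengths)) {
    L <- aln$seqlengths[[s]]
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    eff <- ends - starts + 1
    if (!is.null(mask)) {
      wgr <- GenomicRanges::GRanges(s, IRanges::IRanges(starts, ends))
      ov <- GenomicRanges::intersect(
        wgr, mask[GenomicRanges::seqnames(mask) == s], ignore.strand = TRUE)
      hit <- GenomicRanges::findOverlaps(wgr, ov)
      w <- tapply(GenomicRanges::width(ov)[S4Vectors::subjectHits(hit)],
                  factor(S4Vectors::queryHits(hit), seq_along(wgr)), sum)
      eff <- as.numeric(ifelse(is.na(w), 0, w))
    }
    in_s <- scf_use == s
    widx <- findInterval(pos_use[in_s], starts)
    S <- tabulate(widx[pm[in_s, "segregating"] > 0], nbins = length(starts))
    mism <- tapply(pm[in_s, "mismatch"],
                   factor(widx, levels = seq_along(starts)), sum)
    mism <- as.numeric(ifelse(is.na(mism), 0, mism))
    pi_total <- mism / choose(n, 2)
    theta <- ifelse(eff > 0, S / (sum(1 / seq_len(n - 1L)) * eff), NA_real_)
    D <- rep(NA_real_, length(S))
    nz <- S > 0
    D[nz] <- vapply(which(nz), function(k) tajimas_d(S[k], n, pi_total[k]),
                    numeric(1))
    out[[s]] <- data.frame(
      scaffold = s, start = starts, end = ends, L = eff, n = n, S = S,
      pi = ifelse(eff > 0, pi_total / eff, NA_real_),
      theta_w = theta, tajima_d = D
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Genome-wide pi, optionally masked
#'
#' @param aln An `iupac_alignment`.
#' @param mask Optional [GenomicRanges::GRanges] mask.
#' @param isolates Optional isolate subset.
#' @return pi per site over the (masked) genome.
#' @export
genome_pi <- function(aln, mask = NULL, isolates = NULL) {
  codes <- aln$codes
  if (!is.null(isolates)) codes <- codes[, isolates, drop = FALSE]
  n <- ncol(codes)
  if (n < 2L) undefined_error("pi requires at least 2 sequences")
  use <- rep(TRUE, nrow(codes))
  L <- sum(as.numeric(aln$seqlengths))
  if (!is.null(mask)) {
    gr <- GenomicRanges::GRanges(aln$scaffold,
                                 IRanges::IRanges(aln$pos, aln$pos))
    use <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
    L <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
      mask, ignore.strand = TRUE))))
  }
  if (!any(use)) return(0)
  pm <- .pair_mismatch_rows(codes[use, , drop = FALSE])
  sum(pm[, "mismatch"]) / choose(n, 2) / L
}
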