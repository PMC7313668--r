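# Synthetic-population generator.
#
# Simulation happens at the variant-call level (genotypes, depths, allele
# depths), not at the read level: downstream analyses consume calls, and the
# mapping/calling stack that would produce them from reads is out of scope.
#
# Genome model:
#   * diploid isolate  = two haplotypes D1/D2 of one lineage, heterozygous
#     at `het_rate` sites per kb outside LOH blocks;
#   * triploid isolate = an allotriploid: the D1/D2 diploid subgenome plus a
#     haploid subgenome H diverged from it at `subgenome_divergence` per
#     site. Divergence mutations fall on either lineage with equal
#     probability, so half the subgenome-distinguishing sites carry the
#     variant on H (allele balance 1/3) and half carry it on both diploid
#     copies (balance 2/3) -- which is what produces the twin 0.33/0.66
#     modes in triploid allele-balance histograms.
# Site classes (het / divergence / hom) are mutually exclusive by position.

#' Specify a simulated isolate
#'
#' Collects and validates the generator parameters for one isolate. Defaults
#' reflect a typical diploid of a hybrid yeast cohort: 7.1 heterozygous sites
#' per kb outside LOH, 13% of the genome in LOH blocks of mean 150 kb
#' (minimum 100 kb), and 60x mean depth.
#'
#' @param ploidy 2 (diploid) or 3 (allotriploid).
#' @param het_rate Expected heterozygous sites per kb outside LOH, carried by
#'   the diploid subgenome.
#' @param subgenome_divergence Per-site divergence between the haploid and
#'   diploid subgenomes; required iff `ploidy == 3`.
#' @param loh_fraction Fraction of the genome covered by LOH blocks.
#' @param loh_block_length Mean LOH block length in bases.
#' @param loh_block_min Minimum LOH block length; block lengths are drawn as
#'   `loh_block_min + Exp(loh_block_length - loh_block_min)`.
#' @param hom_rate Expected isolate-private homozygous substitutions per site
#'   (lineage divergence from the reference); placed genome-wide.
#' @param cnv_events `NULL` or a data.frame with columns `scaffold`, `start`,
#'   `end`, `delta_copies` (+1 or -1) and `subgenome`
#'   (`"haploid"`/`"diploid"`, `NA` for diploid isolates).
#' @param aneuploid_scaffolds `NULL` or a data.frame with columns `scaffold`,
#'   `delta_copies` and `subgenome`.
#' @param depth Mean sequencing depth at base ploidy.
#' @param qual_fail_frac Fraction of emitted calls whose QUAL is drawn below
#'   the standard filter threshold of 25.
#' @param id Isolate name used in reports and file names.
#' @param seed Integer seed; all randomness of this isolate derives from it.
#' @return An `isolate_spec` object (validated list).
#' @export
isolate_spec <- function(ploidy = 2L, het_rate = 7.1,
                         subgenome_divergence = NULL,
                         loh_fraction = 0, loh_block_length = 150000,
                         loh_block_min = 100000, hom_rate = 0,
                         cnv_events = NULL, aneuploid_scaffolds = NULL,
                         depth = 60, qual_fail_frac = 0.02,
                         id = "isolate", seed = 1L) {
  stopifnot(ploidy %in% c(2L, 3L), het_rate >= 0,
            loh_fraction >= 0, loh_fraction <= 1,
            loh_block_min > 0, loh_block_length >= loh_block_min,
            hom_rate >= 0, depth > 0,
            qual_fail_frac >= 0, qual_fail_frac < 1)
  if (ploidy == 3L) {
    if (is.null(subgenome_divergence) || subgenome_divergence < 0)
      stop("`subgenome_divergence` is required (>= 0) for triploid isolates")
  } else if (!is.null(subgenome_divergence)) {
    stop("`subgenome_divergence` only applies to triploid isolates")
  }
  if (!is.null(cnv_events)) {
    cnv_events <- as.data.frame(cnv_events)
    need <- c("scaffold", "start", "end", "delta_copies", "subgenome")
    if (!all(need %in% names(cnv_events)))
      stop("cnv_events needs columns: ", paste(need, collapse = ", "))
    if (!all(abs(cnv_events$delta_copies) == 1))
      stop("only single-copy gains/losses (delta_copies = +/-1) are modelled")
  }
  if (!is.null(aneuploid_scaffolds)) {
    aneuploid_scaffolds <- as.data.frame(aneuploid_scaffolds)
    if (!all(c("scaffold", "delta_copies") %in% names(aneuploid_scaffolds)))
      stop("aneuploid_scaffolds needs columns scaffold, delta_copies")
    if (is.null(aneuploid_scaffolds$subgenome))
      aneuploid_scaffolds$subgenome <- NA_character_
  }
  structure(list(
    ploidy = as.integer(ploidy), het_rate = het_rate,
    subgenome_divergence = subgenome_divergence,
    loh_fraction = loh_fraction, loh_block_length = loh_block_length,
    loh_block_min = loh_block_min, hom_rate = hom_rate,
    cnv_events = cnv_events, aneuploid_scaffolds = aneuploid_scaffolds,
    depth = depth, qual_fail_frac = qual_fail_frac,
    id = id, seed = as.integer(seed)
  ), class = "isolate_spec")
}

# Draw non-overlapping LOH blocks totalling fraction * genome length.
# Lengths: min + exponential excess; the final block is trimmed so the truth
# total matches the requested fraction; placement uniform by rejection.
place_loh_blocks <- function(lens, fraction, mean_len, min_len) {
  total <- sum(as.numeric(lens))
  target <- round(fraction * total)
  if (target <= 0) {
    return(GenomicRanges::GRanges(seqlengths = lens))
  }
  excess <- max(mean_len - min_len, 1)
  blk <- numeric(0)
  repeat {
    rem <- target - sum(blk)
    if (rem < min_len) {
      # absorb the remainder into the last block so every block keeps the
      # minimum length and the truth fraction is met exactly
      if (length(blk)) blk[length(blk)] <- blk[length(blk)] + rem
      else blk <- rem
      break
    }
    l <- round(min_len + stats::rexp(1, 1 / excess))
    if (rem - l < min_len) l <- rem
    blk <- c(blk, l)
  }
  blk <- blk[blk >= 1]
  scf <- character(0); st <- numeric(0); en <- numeric(0)
  for (l in sort(blk, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(10000)) {
      s <- sample(names(lens), 1L, prob = as.numeric(lens))
      if (lens[[s]] < l) next
      a <- sample.int(lens[[s]] - l + 1L, 1L)
      b <- a + l - 1L
      same <- scf == s
      if (!any(same & st <= b & en >= a)) {
        scf <- c(scf, s); st <- c(st, a); en <- c(en, b)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place LOH blocks; fraction too high for genome")
  }
  gr <- GenomicRanges::GRanges(scf, IRanges::IRanges(st, en),
                               seqlengths = lens)
  GenomicRanges::sort(gr)
}

# sample n positions uniformly from allowed (TRUE) positions of one scaffold
sample_positions <- function(allowed, n) {
  idx <- which(allowed)
  if (length(idx) < n) n <- length(idx)
  sort(sample(idx, n))
}

random_alt <- function(ref_bases) {
  bases <- c("A", "C", "G", "T")
  # row i = the three alternatives to base i
  alt_choices <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
  n <- length(ref_bases)
  alt_choices[cbind(match(ref_bases, bases),
                    sample.int(3L, n, replace = TRUE))]
}

#' Simulate the true genotype structure of one isolate
#'
#' Places LOH blocks, heterozygous sites (outside LOH), subgenome-distinguishing
#' sites for triploids, and private homozygous substitutions on a reference,
#' recording for every site which genome copies carry the alternate allele.
#' This is the ground truth against which detection stages are scored.
#'
#' @param ref A `ref_genome`.
#' @param spec An [isolate_spec()].
#' @return An `isolate_truth` object: list with `spec`, `id`, `sites` (one row
#'   per true variant site with `class` in het/divergence/hom and `carrier` in
#'   D1/D2/D12/H/ALL), `loh` (GRanges), `cnv` (GRanges with `delta_copies`,
#'   `subgenome`, `copy`, `copy_number`), `aneuploidy` (data.frame) and
#'   `seqlengths`.
#' @export
simulate_isolate <- function(ref, spec) {
  stopifnot(inherits(ref, "ref_genome"), inherits(spec, "isolate_spec"))
  lens <- scaffold_lengths(ref)
  set.seed(spec$seed)

  loh <- place_loh_blocks(lens, spec$loh_fraction,
                          spec$loh_block_length, spec$loh_block_min)

  sites <- list()
  for (s in names(lens)) {
    allowed <- rep(TRUE, lens[[s]])
    loh_s <- loh[GenomicRanges::seqnames(loh) == s]
    if (length(loh_s)) {
      for (k in seq_along(loh_s)) {
        allowed[GenomicRanges::start(loh_s)[k]:GenomicRanges::end(loh_s)[k]] <- FALSE
      }
    }
    n_allowed <- sum(allowed)

    # heterozygous sites of the diploid subgenome, outside LOH
    n_het <- stats::rpois(1L, spec$het_rate / 1000 * n_allowed)
    pos_het <- sample_positions(allowed, n_het)
    allowed[pos_het] <- FALSE
    carrier_het <- sample(c("D1", "D2"), length(pos_het), replace = TRUE)

    # subgenome-distinguishing sites (triploids), outside LOH, off het sites
    pos_div <- integer(0); carrier_div <- character(0)
    if (spec$ploidy == 3L) {
      n_div <- stats::rpois(1L, spec$subgenome_divergence * sum(allowed))
      pos_div <- sample_positions(allowed, n_div)
      allowed[pos_div] <- FALSE
      # derived allele on the haploid lineage (H) or the diploid lineage (D12)
      carrier_div <- sample(c("H", "D12"), length(pos_div), replace = TRUE)
    }

    # private homozygous substitutions: genome-wide, including LOH
    pos_hom <- integer(0)
    if (spec$hom_rate > 0) {
      allowed_hom <- rep(TRUE, lens[[s]])
      allowed_hom[c(pos_het, pos_div)] <- FALSE
      n_hom <- stats::rpois(1L, spec$hom_rate * lens[[s]])
      pos_hom <- sample_positions(allowed_hom, n_hom)
    }

    pos <- c(pos_het, pos_div, pos_hom)
    if (!length(pos)) next
    cls <- c(rep("het", length(pos_het)), rep("divergence", length(pos_div)),
             rep("hom", length(pos_hom)))
    car <- c(carrier_het, carrier_div, rep("ALL", length(pos_hom)))
    o <- order(pos)
    rb <- ref_base_at(ref, rep(s, length(pos)), pos[o])
    sites[[s]] <- data.frame(
      scaffold = s, pos = pos[o], ref = rb, alt = random_alt(rb),
      class = cls[o], carrier = car[o], stringsAsFactors = FALSE
    )
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(scaffold = character(), pos = integer(), ref = character(),
               alt = character(), class = character(), carrier = character())
  rownames(sites) <- NULL

  cnv <- validate_events(spec, lens)
  truth <- structure(list(
    spec = spec, id = spec$id, sites = sites, loh = loh, cnv = cnv,
    aneuploidy = spec$aneuploid_scaffolds, seqlengths = lens
  ), class = "isolate_truth")
  truth
}

# turn spec$cnv_events into a truth GRanges, fixing which physical copy each
# event duplicates/removes (D1/D2/H) so allele counts are well defined
validate_events <- function(spec, lens) {
  ev <- spec$cnv_events
  if (is.null(ev) || !nrow(ev)) {
    return(GenomicRanges::GRanges(seqlengths = lens))
  }
  if (!all(ev$scaffold %in% names(lens)))
    stop("cnv event on unknown scaffold")
  if (any(ev$start < 1 | ev$end > lens[ev$scaffold] | ev$start > ev$end))
    stop("cnv event outside scaffold bounds")
  copy <- character(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    sg <- ev$subgenome[k]
    if (spec$ploidy == 2L || is.na(sg)) {
      copy[k] <- sample(c("D1", "D2"), 1L)
    } else if (sg == "haploid") {
      copy[k] <- "H"
    } else if (sg == "diploid") {
      copy[k] <- sample(c("D1", "D2"), 1L)
    } else stop("subgenome must be 'haploid', 'diploid' or NA")
  }
  gr <- GenomicRanges::GRanges(ev$scaffold,
                               IRanges::IRanges(ev$start, ev$end),
                               seqlengths = lens)
  gr$delta_copies <- as.integer(ev$delta_copies)
  gr$subgenome <- ifelse(is.na(ev$subgenome), "diploid", ev$subgenome)
  gr$copy <- copy
  gr$copy_number <- spec$ploidy + gr$delta_copies
  if (length(GenomicRanges::reduce(gr)) != length(gr))
    stop("cnv events must not overlap")
  GenomicRanges::sort(gr)
}

# per-copy multiplicity at each site of `sites`, after CNV + aneuploidy
# overlay; returns matrix with columns D1, D2, H
copy_multiplicity <- function(truth) {
  sites <- truth$sites
  ploidy <- truth$spec$ploidy
  mult <- matrix(rep(c(1L, 1L, if (ploidy == 3L) 1L else 0L),
                     each = nrow(sites)),
                 nrow = nrow(sites), dimnames = list(NULL, c("D1", "D2", "H")))
  apply_delta <- function(idx, copy, delta) {
    mult[idx, copy] <<- pmax(mult[idx, copy] + delta, 0L)
  }
  an <- truth$aneuploidy
  if (!is.null(an) && nrow(an)) {
    for (k in seq_len(nrow(an))) {
      idx <- sites$scaffold == an$scaffold[k]
      sg <- an$subgenome[k]
      copy <- if (truth$spec$ploidy == 3L && !is.na(sg) && sg == "haploid")
        "H" else "D1"
      apply_delta(idx, copy, as.integer(an$delta_copies[k]))
    }
  }
  cnv <- truth$cnv
  if (length(cnv)) {
    for (k in seq_along(cnv)) {
      idx <- sites$scaffold == as.character(GenomicRanges::seqnames(cnv)[k]) &
        sites$pos >= GenomicRanges::start(cnv)[k] &
        sites$pos <= GenomicRanges::end(cnv)[k]
      apply_delta(idx, cnv$copy[k], cnv$delta_copies[k])
    }
  }
  mult
}

# true alt-copy and total-copy counts at every site
site_copy_counts <- function(truth) {
  sites <- truth$sites
  mult <- copy_multiplicity(truth)
  total <- rowSums(mult)
  alt <- integer(nrow(sites))
  alt[sites$carrier == "D1"] <- mult[sites$carrier == "D1", "D1"]
  alt[sites$carrier == "D2"] <- mult[sites$carrier == "D2", "D2"]
  alt[sites$carrier == "H"] <- mult[sites$carrier == "H", "H"]
  d12 <- sites$carrier == "D12"
  alt[d12] <- mult[d12, "D1"] + mult[d12, "D2"]
  allc <- sites$carrier == "ALL"
  alt[allc] <- total[allc]
  cbind(alt = alt, total = total)
}

#' Simulate variant calls and a depth track from isolate truth
#'
#' Emulates the output of a short-read calling pipeline run with diploid
#' genotype calls: per-site depth is Poisson at the local copy number, the
#' alternate-read count is binomial at the true allele fraction, and QUAL is
#' drawn so a configurable fraction of calls falls below the standard filter
#' threshold (25). Sites whose alternate allele has been deleted by a CNV are
#' not emitted (they revert to reference).
#'
#' @param truth An [simulate_isolate()] result.
#' @param depth_track If `TRUE`, also simulate a per-position depth track.
#' @return List with `records` (variant-call data.frame with columns
#'   `scaffold`, `pos`, `ref`, `alt`, `genotype`, `depth`, `alt_depth`,
#'   `qual`) and `depth` (a `coverage_track` or `NULL`).
#' @export
simulate_calls <- function(truth, depth_track = TRUE) {
  stopifnot(inherits(truth, "isolate_truth"))
  spec <- truth$spec
  set.seed(derive_seed(spec$seed, 1L))
  sites <- truth$sites
  cc <- site_copy_counts(truth)
  keep <- cc[, "alt"] > 0 & cc[, "total"] > 0
  sites <- sites[keep, , drop = FALSE]
  cc <- cc[keep, , drop = FALSE]

  n <- nrow(sites)
  d <- stats::rpois(n, spec$depth * cc[, "total"] / spec$ploidy)
  emitted <- d > 0
  sites <- sites[emitted, , drop = FALSE]
  cc <- cc[emitted, , drop = FALSE]
  d <- d[emitted]
  n <- length(d)
  ad <- stats::rbinom(n, d, cc[, "alt"] / cc[, "total"])
  geno <- ifelse(cc[, "alt"] == cc[, "total"], "hom_alt", "het")
  fail <- stats::runif(n) < spec$qual_fail_frac
  qual <- ifelse(fail, stats::runif(n, 0, 25),
                 25 + stats::rgamma(n, shape = 2, scale = 30))
  records <- data.frame(
    scaffold = sites$scaffold, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    genotype = geno, depth = d, alt_depth = ad, qual = round(qual, 2),
    stringsAsFactors = FALSE
  )

  track <- NULL
  if (depth_track) {
    lens <- truth$seqlengths
    depth_list <- lapply(names(lens), function(s) {
      cn <- rep(spec$ploidy, lens[[s]])
      an <- truth$aneuploidy
      if (!is.null(an) && nrow(an)) {
        for (k in which(an$scaffold == s))
          cn <- cn + as.integer(an$delta_copies[k])
      }
      cnv <- truth$cnv
      cnv_s <- cnv[GenomicRanges::seqnames(cnv) == s]
      for (k in seq_along(cnv_s)) {
        i <- GenomicRanges::start(cnv_s)[k]:GenomicRanges::end(cnv_s)[k]
        cn[i] <- cn[i] + cnv_s$delta_copies[k]
      }
      stats::rpois(lens[[s]], spec$depth * pmax(cn, 0) / spec$ploidy)
    })
    names(depth_list) <- names(lens)
    track <- coverage_track(depth_list, bin_size = 1L)
  }
  list(records = records, depth = track)
}

#' Draw random CNV events for a simulated isolate
#'
#' Segmental events with exponential lengths (default mean 350 kb, the scale
#' of segmental duplications/losses seen in hybrid yeast genomes), placed
#' without overlap; for triploids the affected subgenome is drawn uniformly.
#'
#' @param ref A `ref_genome`.
#' @param n Number of events.
#' @param mean_length Mean event length in bases.
#' @param min_length Minimum event length.
#' @param p_gain Probability an event is a gain (+1) rather than a loss (-1).
#' @param ploidy Isolate ploidy (controls subgenome labelling).
#' @param seed Integer seed.
#' @return data.frame suitable for `cnv_events` of [isolate_spec()].
#' @export
random_cnv_events <- function(ref, n, mean_length = 350000,
                              min_length = 50000, p_gain = 0.5,
                              ploidy = 2L, seed = 1L) {
  if (n == 0) return(NULL)
  lens <- scaffold_lengths(ref)
  set.seed(seed)
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place CNV events without overlap")
    l <- round(min_length + stats::rexp(1, 1 / max(mean_length - min_length, 1)))
    s <- sample(names(lens), 1L, prob = as.numeric(lens))
    if (lens[[s]] < l + 2) next
    a <- sample.int(lens[[s]] - l, 1L)
    b <- a + l - 1L
    if (!is.null(out) &&
        any(out$scaffold == s & out$start <= b & out$end >= a)) next
    ev <- data.frame(
      scaffold = s, start = a, end = b,
      delta_copies = if (stats::runif(1) < p_gain) 1L else -1L,
      subgenome = if (ploidy == 3L)
        sample(c("haploid", "diploid"), 1L) else NA_character_,
      stringsAsFactors = FALSE
    )
    out <- rbind(out, ev)
  }
  out
}

#' Simulate a structured cohort of isolates
#'
#' Generates a cohort with shared polymorphism so that between-isolate
#' diversity statistics and phylogenies are meaningful. Between-isolate
#' variation has three additive layers, each of homozygous substitutions:
#' cohort-wide segregating sites drawn from the neutral site-frequency
#' spectrum (`sfs_theta`, gives E\[pi\] = `sfs_theta` and E\[Tajima's D\] ~ 0),
#' cluster-private substitutions shared by every member of a cluster
#' (`cluster_divergence`), and isolate-private substitutions
#' (`isolate_divergence`). Within-isolate heterozygosity and triploid
#' subgenome structure come from [simulate_isolate()] per isolate.
#'
#' If `target_pi` is given, `sfs_theta` is set to
#' `target_pi - het_rate/1000`: under IUPAC average-state comparison each
#' heterozygous site contributes exactly 0.5 to every pairwise comparison, so
#' cohort-wide pi decomposes as `sfs_theta + het_rate/1000` (an identity, not
#' a fit).
#'
#' @param ref A `ref_genome`.
#' @param cluster_sizes Integer vector, isolates per cluster.
#' @param ploidy Integer vector (per cluster) of ploidies.
#' @param het_rate Het sites per kb (scalar or per cluster).
#' @param subgenome_divergence Per-site subgenome divergence for triploid
#'   clusters.
#' @param loh_fraction LOH genome fraction (scalar or per cluster).
#' @param sfs_theta Per-site theta of cohort-wide neutral segregating sites.
#' @param target_pi If non-`NULL`, overrides `sfs_theta` as described above.
#' @param cluster_divergence Per-site rate of cluster-private substitutions.
#' @param isolate_divergence Per-site rate of isolate-private substitutions.
#' @param depth Mean depth (scalar or per cluster).
#' @param qual_fail_frac See [isolate_spec()].
#' @param seed Integer master seed.
#' @return List with `truths` (list of `isolate_truth`), `clusters` (named
#'   cluster label per isolate) and `ids`.
#' @export
simulate_cohort <- function(ref, cluster_sizes, ploidy = 2L,
                            het_rate = 7.1, subgenome_divergence = 0.024,
                            loh_fraction = 0, sfs_theta = 0,
                            target_pi = NULL,
                            cluster_divergence = 0, isolate_divergence = 0,
                            depth = 60, qual_fail_frac = 0.02, seed = 1L) {
  k <- length(cluster_sizes)
  ploidy <- rep_len(ploidy, k)
  het_rate <- rep_len(het_rate, k)
  loh_fraction <- rep_len(loh_fraction, k)
  depth <- rep_len(depth, k)
  n <- sum(cluster_sizes)
  if (!is.null(target_pi)) {
    if (length(unique(het_rate)) > 1L)
      stop("target_pi calibration assumes a single cohort-wide het_rate")
    sfs_theta <- target_pi - het_rate[1L] / 1000
    if (sfs_theta < 0)
      stop("target_pi below the heterozygosity floor het_rate/1000")
  }
  lens <- scaffold_lengths(ref)
  total <- sum(as.numeric(lens))

  cluster_of <- rep(seq_len(k), cluster_sizes)
  ids <- sprintf("iso_%02d", seq_len(n))

  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- cluster_of[i]
    sp <- isolate_spec(
      ploidy = ploidy[cl], het_rate = het_rate[cl],
      # subgenome-distinguishing sites are cluster-shared (all members carry
      # the same hybrid haploid lineage) and injected below
      subgenome_divergence = if (ploidy[cl] == 3L) 0 else NULL,
      loh_fraction = loh_fraction[cl],
      hom_rate = isolate_divergence,
      depth = depth[cl], qual_fail_frac = qual_fail_frac,
      id = ids[i], seed = derive_seed(seed, 100L + i)
    )
    truths[[i]] <- simulate_isolate(ref, sp)
  }

  # shared hom substitutions appended to member truth tables
  set.seed(derive_seed(seed, 7L))
  shared <- list()
  if (sfs_theta > 0 && n >= 2L) {
    a1 <- sum(1 / seq_len(n - 1L))
    n_sites <- stats::rpois(1L, sfs_theta * a1 * total)
    if (n_sites > 0) {
      counts <- sample(seq_len(n - 1L), n_sites, replace = TRUE,
                       prob = 1 / seq_len(n - 1L))
      shared[["sfs"]] <- list(counts = counts,
                              members = lapply(counts, sample.int, n = n))
    }
  }
  add_block <- function(truths, member_idx, n_sites, class = "hom",
                        carrier = "ALL") {
    if (n_sites == 0) return(truths)
    scf <- sample(names(lens), n_sites, replace = TRUE,
                  prob = as.numeric(lens))
    pos <- vapply(scf, function(s) sample.int(lens[[s]], 1L), integer(1))
    rb <- ref_base_at(ref, scf, pos)
    ab <- random_alt(rb)
    if (identical(carrier, "divergence_mix"))
      carrier <- sample(c("H", "D12"), n_sites, replace = TRUE)
    add <- data.frame(scaffold = scf, pos = pos, ref = rb, alt = ab,
                      class = class, carrier = carrier,
                      stringsAsFactors = FALSE)
    add <- add[!duplicated(paste(add$scaffold, add$pos)), , drop = FALSE]
    for (i in member_idx) {
      tr <- truths[[i]]
      keep <- !(paste(add$scaffold, add$pos) %in%
                  paste(tr$sites$scaffold, tr$sites$pos))
      tr$sites <- rbind(tr$sites, add[keep, , drop = FALSE])
      o <- order(match(tr$sites$scaffold, names(lens)), tr$sites$pos)
      tr$sites <- tr$sites[o, , drop = FALSE]
      rownames(tr$sites) <- NULL
      truths[[i]] <- tr
    }
    truths
  }
  if (!is.null(shared[["sfs"]])) {
    sfs <- shared[["sfs"]]
    # group sites by their carrier subset to batch the appends
    key <- vapply(sfs$members, function(m) paste(sort(m), collapse = ","),
                  character(1))
    for (kk in unique(key)) {
      members <- as.integer(strsplit(kk, ",")[[1]])
      truths <- add_block(truths, members, sum(key == kk))
    }
  }
  if (cluster_divergence > 0) {
    for (cl in seq_len(k)) {
      n_sites <- stats::rpois(1L, cluster_divergence * total)
      truths <- add_block(truths, which(cluster_of == cl), n_sites)
    }
  }
  # cluster-shared subgenome-distinguishing sites for triploid clusters
  for (cl in which(ploidy == 3L)) {
    n_sites <- stats::rpois(1L, subgenome_divergence * total)
    truths <- add_block(truths, which(cluster_of == cl), n_sites,
                        class = "divergence", carrier = "divergence_mix")
  }
  list(truths = truths,
       clusters = stats::setNames(sprintf("C%d", cluster_of), ids),
       ids = ids)
}

#' Write a complete analysis fixture to disk
#'
#' Emits everything the pipeline consumes: the reference FASTA, a gene-model
#' GFF3 (genes tiled at configurable density), one VCF and one depth TSV per
#' isolate, and BED files of the true LOH blocks and CNV segments for
#' parameter-recovery checks.
#'
#' @param cohort List of `isolate_truth` objects (or a [simulate_cohort()]
#'   result).
#' @param ref The `ref_genome` the cohort was simulated on.
#' @param outdir Output directory (created if absent).
#' @param gene_length,intergenic Gene tiling density, see [tile_genes()].
#' @param depth_bin Bin size of the emitted depth TSV (1 = per position).
#' @return Invisibly, a named list of written paths.
#' @export
write_fixture_set <- function(cohort, ref, outdir, gene_length = 1500L,
                              intergenic = 500L, depth_bin = 1L) {
  if (!is.null(cohort$truths)) cohort <- cohort$truths
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- list()
  paths$fasta <- write_reference_fasta(ref, file.path(outdir, "reference.fasta"))
  genes <- tile_genes(ref, gene_length, intergenic)
  paths$gff3 <- write_genes_gff3(genes, file.path(outdir, "genes.gff3"))
  lens <- scaffold_lengths(ref)
  loh_all <- GenomicRanges::GRangesList()
  cnv_all <- GenomicRanges::GRangesList()
  for (tr in cohort) {
    calls <- simulate_calls(tr)
    vcf <- file.path(outdir, paste0(tr$id, ".vcf"))
    write_vcf(calls$records, vcf, sample = tr$id, seqlengths = lens)
    paths[[paste0("vcf_", tr$id)]] <- vcf
    tsv <- file.path(outdir, paste0(tr$id, "_depth.tsv"))
    write_depth_tsv(bin_track(calls$depth, depth_bin), tsv)
    paths[[paste0("depth_", tr$id)]] <- tsv
    if (length(tr$loh)) {
      g <- tr$loh; g$isolate <- tr$id
      loh_all[[tr$id]] <- g
    }
    if (length(tr$cnv)) {
      g <- tr$cnv
      S4Vectors::mcols(g) <- S4Vectors::DataFrame(isolate = tr$id)
      cnv_all[[tr$id]] <- g
    }
  }
  write_truth_bed <- function(grl, path) {
    gr <- unlist(grl, use.names = FALSE)
    if (!length(gr)) gr <- GenomicRanges::GRanges(seqlengths = lens)
    nm <- if (length(gr)) gr$isolate else character(0)
    S4Vectors::mcols(gr) <- NULL
    if (length(gr)) gr$name <- nm
    rtracklayer::export(gr, path, format = "bed")
    path
  }
  paths$loh_bed <- write_truth_bed(loh_all, file.path(outdir, "truth_loh.bed"))
  paths$cnv_bed <- write_truth_bed(cnv_all, file.path(outdir, "truth_cnv.bed"))
  invisible(paths)
}
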