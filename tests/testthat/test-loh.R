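# LOH sliding-window scan and heterozygosity accounting.

# naive reference scan: enumerate every window on the same grid, flag, and
# merge by interval union -- independent of the package implementation
brute_scan <- function(pos, L, window = 50000, step = 25000, max_het = 10) {
  starts <- seq(1, L, by = step)
  keep <- list()
  for (st in starts) {
    en <- min(st + window - 1, L)
    if (st > max(L - window + 1, 1) || en - st + 1 == window) {
      thr <- floor(max_het * (en - st + 1) / window)
    } else thr <- max_het
    if (sum(pos >= st & pos <= en) <= thr) keep[[length(keep) + 1]] <- c(st, en)
  }
  if (!length(keep)) return(NULL)
  m <- do.call(rbind, keep)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    last <- nrow(merged)
    if (m[i, 1] <= merged[last, 2] + 1) {
      merged[last, 2] <- max(merged[last, 2], m[i, 2])
    } else merged <- rbind(merged, m[i, ])
  }
  merged
}

lens1 <- c(scf_1 = 500000)

test_that("an isolate with no het sites is one whole-scaffold region", {
  lens <- c(scf_1 = 120000, scf_2 = 80000)
  loh <- scan_loh(list(), lens)
  expect_identical(length(loh), 2L)
  expect_identical(as.numeric(GenomicRanges::width(loh)),
                   unname(lens))
})

test_that("eleven het sites in a 50-kb window prevent flagging", {
  # scaffold = exactly one window
  lens <- c(scf_1 = 50000)
  # 11 sites in the full window, 6 of them in the 25-kb tail window (whose
  # prorated threshold is 5): nothing is flagged
  eleven <- c(round(seq(2000, 24000, length.out = 5)),
              round(seq(26000, 49000, length.out = 6)))
  expect_identical(length(scan_loh(list(scf_1 = eleven), lens)), 0L)
  # dropping one site to 10 flags the full 50-kb window
  ten <- eleven[-1]
  expect_identical(length(scan_loh(list(scf_1 = ten), lens)), 1L)
})

test_that("partial terminal windows use a prorated threshold", {
  # 75-kb scaffold: tail window [50001, 75000] has threshold floor(10/2) = 5
  lens <- c(scf_1 = 75000)
  dense <- round(seq(500, 49500, length.out = 100))
  six_tail <- round(seq(51000, 74000, length.out = 6))
  expect_identical(length(scan_loh(list(scf_1 = c(dense, six_tail)), lens)),
                   0L)
  five_tail <- six_tail[-1]
  loh <- scan_loh(list(scf_1 = c(dense, five_tail)), lens,
                  refine_boundaries = FALSE)
  expect_identical(length(loh), 1L)
  expect_identical(GenomicRanges::start(loh), 50001L)
})

test_that("raw scan matches the exhaustive window-enumeration oracle", {
  for (s in 1:5) {
    set.seed(s)
    # uniform het background with a deliberate desert
    pos <- sort(c(sample(1:200000, rpois(1, 200000 * 0.007)),
                  sample(300001:500000, rpois(1, 200000 * 0.007))))
    got <- scan_loh(list(scf_1 = pos), lens1, refine_boundaries = FALSE)
    want <- brute_scan(pos, 500000)
    expect_identical(length(got), nrow(want))
    expect_identical(GenomicRanges::start(got), as.integer(want[, 1]))
    expect_identical(GenomicRanges::end(got), as.integer(want[, 2]))
  }
})

test_that("boundary refinement recovers the true desert edges", {
  set.seed(6)
  desert <- c(200001, 320000)
  pos <- sort(sample(c(1:(desert[1] - 1), (desert[2] + 1):500000),
                     rpois(1, 0.007 * (500000 - diff(desert)))))
  pos <- unique(pos)
  loh <- scan_loh(list(scf_1 = pos), lens1)
  expect_identical(length(loh), 1L)
  expect_identical(GenomicRanges::start(loh), max(pos[pos <= desert[1]]) + 1L)
  expect_identical(GenomicRanges::end(loh), min(pos[pos > desert[2]]) - 1L)
})

test_that("the scan is independent of scaffold batching and monotone in max_het", {
  set.seed(7)
  lens <- c(scf_1 = 300000, scf_2 = 200000)
  pos <- list(scf_1 = sort(sample(1:300000, 1200)),
              scf_2 = sort(sample(c(1:50000, 150001:200000), 500)))
  both <- scan_loh(pos, lens)
  one <- scan_loh(pos["scf_1"], c(scf_1 = 300000))
  two <- scan_loh(pos["scf_2"], c(scf_2 = 200000))
  expect_identical(
    as.numeric(c(GenomicRanges::start(one), GenomicRanges::start(two))),
    as.numeric(GenomicRanges::start(both)))

  flagged_total <- vapply(c(5, 10, 20, 50), function(mh) {
    sum(as.numeric(GenomicRanges::width(
      scan_loh(pos, lens, max_het = mh))))
  }, numeric(1))
  expect_true(all(diff(flagged_total) >= 0))
})

test_that("heterozygosity excluding LOH follows the masking algebra", {
  lens <- c(scf_1 = 1000000)
  set.seed(8)
  pos <- sort(sample(1:1000000, 7100))
  expect_equal(heterozygosity_excluding_loh(list(scf_1 = pos),
                                            GenomicRanges::GRanges(),
                                            lens), 7.1)

  # half the genome LOH, all het outside: rate doubles
  half <- GenomicRanges::GRanges("scf_1", IRanges::IRanges(500001, 1000000))
  pos_out <- pos[pos <= 500000]
  whole_rate <- length(pos_out) / 1000
  expect_equal(heterozygosity_excluding_loh(list(scf_1 = pos_out), half, lens),
               2 * whole_rate)

  full <- GenomicRanges::GRanges("scf_1", IRanges::IRanges(1, 1000000))
  expect_error(heterozygosity_excluding_loh(list(scf_1 = pos), full, lens),
               class = "hybridscan_undefined")
})

test_that("loh_genome_fraction equals the interval-union oracle", {
  lens <- c(scf_1 = 1000000)
  expect_identical(loh_genome_fraction(GenomicRanges::GRanges(), lens), 0)
  one <- GenomicRanges::GRanges("scf_1", IRanges::IRanges(1000, 130999))
  expect_equal(loh_genome_fraction(one, lens), 0.13)

  set.seed(9)
  st <- sample(1:900000, 40)
  gr <- GenomicRanges::GRanges("scf_1",
                               IRanges::IRanges(st, st + sample(1000:50000, 40)))
  covered <- logical(1000000)
  for (i in seq_along(gr))
    covered[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  expect_equal(loh_genome_fraction(gr, lens), mean(covered))
})

test_that("detected LOH recovers simulated truth with few false calls", {
  # 8 replicates at 1 Mb (scaled from the 20 x 2 Mb property run to keep the
  # default suite fast); blocks >= 100 kb as in the stated cohort
  ref <- small_ref(c(500000L, 500000L), seed = 50)
  recall <- fp <- numeric(0)
  for (s in 1:8) {
    tr <- quick_isolate(ref, het_rate = 7.1, loh_fraction = 0.13,
                        loh_block_length = 150000, loh_block_min = 100000,
                        depth = 60, seed = 60 + s)
    recs <- filter_calls(simulate_calls(tr, depth_track = FALSE)$records)
    loh <- scan_loh(het_positions(recs), ref)
    truth <- tr$loh
    inter <- GenomicRanges::intersect(loh, truth, ignore.strand = TRUE)
    tp <- sum(as.numeric(GenomicRanges::width(inter)))
    recall <- c(recall, tp / sum(as.numeric(GenomicRanges::width(truth))))
    fp <- c(fp, (sum(as.numeric(GenomicRanges::width(loh))) - tp) /
              (ref$total_length - sum(as.numeric(GenomicRanges::width(truth)))))
  }
  expect_true(all(recall >= 0.95))
  expect_true(all(fp <= 0.01))
})
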