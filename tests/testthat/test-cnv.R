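# Copy-number segmentation, aneuploidy, gene CN, subgenome attribution,
# pangenome classification.

test_that("normalize_ratios matches direct mean/median computation", {
  flat <- coverage_track(list(s = rep(50, 40000)), 1L)
  r <- normalize_ratios(flat, window = 1000, step = 200, edge_exclusion = 2000)
  expect_true(all(r$ratio == 1))
  expect_true(all(r$excluded == (r$start <= 2000 | r$end > 38000)))

  dbl <- rep(50, 40000); dbl[20001:21000] <- 100
  r2 <- normalize_ratios(coverage_track(list(s = dbl), 1L),
                         window = 1000, step = 200, edge_exclusion = 2000)
  expect_equal(r2$ratio[r2$start == 20001], 2)

  set.seed(21)
  d <- rpois(30000, 60)
  r3 <- normalize_ratios(coverage_track(list(s = d), 1L),
                         window = 1000, step = 500, edge_exclusion = 1000)
  # brute force: every window mean over the raw vector, then median scaling
  means <- vapply(r3$start, function(st) mean(d[st:(st + 999)]), numeric(1))
  expect_equal(r3$mean_depth, means)
  expect_equal(r3$ratio, means / median(means))

  expect_error(normalize_ratios(coverage_track(list(s = rep(0, 40000)), 1L),
                                edge_exclusion = 2000), "median")
  expect_error(normalize_ratios(coverage_track(list(s = rep(10, 5000)), 1L)),
               "edge exclusion")
})

test_that("segment_cn recovers simulated segments with tight boundaries", {
  ref <- small_ref(c(300000L), seed = 40)
  # diploid, constant coverage: one neutral CN-2 segment tiling the span
  tr0 <- quick_isolate(ref, het_rate = 1, depth = 60, seed = 41)
  track <- simulate_calls(tr0)$depth
  segs0 <- segment_cn(normalize_ratios(track), 2L)
  expect_identical(length(segs0), 1L)
  expect_identical(segs0$klass, "neutral")
  expect_identical(segs0$copy_number, 2L)
  # tiling invariant: segments cover the non-excluded span exactly
  ratios <- normalize_ratios(track)
  span <- range(c(ratios$start[!ratios$excluded], ratios$end[!ratios$excluded]))
  expect_identical(c(GenomicRanges::start(segs0), GenomicRanges::end(segs0)),
                   as.integer(span))

  # diploid with a 100-kb gain at 1.5x -> CN 3, boundaries within 2 kb
  ev <- data.frame(scaffold = "scf_1", start = 100001, end = 200000,
                   delta_copies = 1L, subgenome = NA)
  tr1 <- quick_isolate(ref, het_rate = 1, depth = 60, cnv_events = ev,
                       seed = 42)
  segs1 <- segment_cn(normalize_ratios(simulate_calls(tr1)$depth), 2L)
  gain <- segs1[segs1$klass == "gain"]
  expect_identical(length(gain), 1L)
  expect_identical(gain$copy_number, 3L)
  expect_lt(abs(GenomicRanges::start(gain) - 100001), 2000)
  expect_lt(abs(GenomicRanges::end(gain) - 200000), 2000)
  expect_identical(sum(as.numeric(GenomicRanges::width(segs1))),
                   diff(span) + 1)

  # triploid with a 100-kb stretch at 2/3 coverage -> CN 2 loss
  ev2 <- data.frame(scaffold = "scf_1", start = 100001, end = 200000,
                    delta_copies = -1L, subgenome = "haploid")
  tr2 <- quick_isolate(ref, ploidy = 3L, het_rate = 1,
                       subgenome_divergence = 0.001, depth = 90,
                       cnv_events = ev2, seed = 43)
  segs2 <- segment_cn(normalize_ratios(simulate_calls(tr2)$depth), 3L)
  loss <- segs2[segs2$klass == "loss"]
  expect_identical(loss$copy_number, 2L)
  expect_lt(abs(GenomicRanges::start(loss) - 100001), 2000)
})

test_that("sub-minimum segments are absorbed into their flank", {
  set.seed(44)
  d <- rpois(200000, 60)
  d[90001:94000] <- rpois(4000, 90)  # 4-kb blip below the 10-kb minimum
  segs <- segment_cn(normalize_ratios(coverage_track(list(s = d), 1L)), 2L)
  expect_identical(length(segs), 1L)
  expect_identical(segs$copy_number, 2L)
})

test_that("detect_aneuploidy calls whole-scaffold gains only", {
  set.seed(45)
  mk <- function(mult) rpois(200000, 60 * mult)
  track <- coverage_track(list(scf_1 = mk(1), scf_2 = mk(1.5),
                               scf_3 = mk(1)), 1L)
  calls <- detect_aneuploidy(coverage_windows(track, 20000), 2L)
  expect_identical(calls$call[calls$scaffold == "scf_2"], "gained")
  expect_identical(calls$call[calls$scaffold != "scf_2"],
                   rep("euploid", 2))
  expect_identical(calls$copy_number[calls$scaffold == "scf_2"], 3L)

  # a 30% segmental stretch does not make an aneuploidy
  seg <- mk(1); seg[1:60000] <- rpois(60000, 90)
  calls2 <- detect_aneuploidy(
    coverage_windows(coverage_track(list(scf_1 = seg), 1L), 20000), 2L)
  expect_identical(calls2$call, "euploid")

  flat <- detect_aneuploidy(
    coverage_windows(coverage_track(list(a = mk(1), b = mk(1)), 1L), 20000),
    2L)
  expect_true(all(flat$call == "euploid"))
})

test_that("gene_copy_number follows the >50% overlap rule", {
  genes <- GenomicRanges::GRanges("s", IRanges::IRanges(
    c(1000, 5000, 9000), width = 1000))
  genes$gene_id <- c("g_in", "g_40", "g_51")
  segments <- GenomicRanges::GRanges(
    "s", IRanges::IRanges(c(500, 5601, 8490), c(2500, 6500, 9510)))
  segments$copy_number <- c(3L, 3L, 0L)
  segments$klass <- c("gain", "gain", "loss")
  segments$mean_ratio <- c(1.5, 1.5, 0)
  cn <- gene_copy_number(segments, genes, 2L)
  expect_identical(cn$copy_number[cn$gene_id == "g_in"], 3L)   # fully inside
  expect_identical(cn$klass[cn$gene_id == "g_in"], "duplicated")
  expect_identical(cn$copy_number[cn$gene_id == "g_40"], 2L)   # 40% overlap
  expect_identical(cn$klass[cn$gene_id == "g_40"], "unchanged")
  expect_identical(cn$copy_number[cn$gene_id == "g_51"], 0L)   # 51% in CN 0
  expect_identical(cn$klass[cn$gene_id == "g_51"], "lost")
})

test_that("subgenome attribution is correct for all four configurations", {
  ref <- small_ref(c(400000L), seed = 46)
  cases <- list(
    list(delta = 1L, subgenome = "diploid", expect = "3:1"),
    list(delta = 1L, subgenome = "haploid", expect = "2:2"),
    list(delta = -1L, subgenome = "haploid", expect = "2:0"),
    list(delta = -1L, subgenome = "diploid", expect = "1:1")
  )
  for (case in cases) {
    for (s in 1:5) {
      ev <- data.frame(scaffold = "scf_1", start = 100001, end = 250000,
                       delta_copies = case$delta, subgenome = case$subgenome)
      tr <- quick_isolate(ref, ploidy = 3L, het_rate = 10,
                          subgenome_divergence = 0.024, depth = 100,
                          cnv_events = ev, seed = 300 + 10 * case$delta + s)
      recs <- filter_calls(simulate_calls(tr, depth_track = FALSE)$records)
      inside <- recs$scaffold == "scf_1" & recs$pos >= 100001 &
        recs$pos <= 250000
      att <- subgenome_attribution(if (case$delta > 0) "gain" else "loss",
                                   allele_balance(recs[inside, ]))
      expect_identical(att$configuration, case$expect)
    }
  }

  few <- subgenome_attribution("gain", runif(5))
  expect_identical(few$configuration, "unresolved")
  expect_match(few$reason, "minimum")
})

test_that("core_accessory equals the column-minimum oracle", {
  m <- matrix(2L, nrow = 5, ncol = 3,
              dimnames = list(paste0("g", 1:5), paste0("i", 1:3)))
  all_present <- core_accessory(m)
  expect_identical(all_present$accessory, 0L)

  m["g3", "i2"] <- 0L
  one <- core_accessory(m)
  expect_identical(one$accessory, 1L)
  expect_identical(one$classes$class[one$classes$gene_id == "g3"],
                   "accessory")

  set.seed(47)
  rnd <- matrix(sample(0:4, 300, TRUE, prob = c(0.1, 0.2, 0.4, 0.2, 0.1)),
                nrow = 50, dimnames = list(paste0("g", 1:50), paste0("i", 1:6)))
  got <- core_accessory(rnd)
  want_core <- apply(rnd, 1, min) >= 1
  expect_identical(got$core, sum(want_core))
  expect_identical(got$classes$class,
                   unname(ifelse(want_core, "core", "accessory")))
})

test_that("triploids carry a larger gene-CNV burden than diploids", {
  # event-rate contrast as reported (triploids ~5.6x more CNVs); 3 replicates
  ref <- small_ref(c(400000L, 400000L), seed = 48)
  genes <- tile_genes(ref)
  for (s in 1:3) {
    n_var <- function(ploidy, n_events, seed) {
      ev <- random_cnv_events(ref, n_events, mean_length = 60000,
                              min_length = 30000, ploidy = ploidy,
                              seed = seed)
      tr <- quick_isolate(ref, ploidy = ploidy, het_rate = 2,
                          subgenome_divergence = if (ploidy == 3L) 0.01,
                          depth = 60, cnv_events = ev, seed = seed)
      segs <- segment_cn(normalize_ratios(simulate_calls(tr)$depth), ploidy)
      sum(gene_copy_number(segs, genes, ploidy)$klass != "unchanged")
    }
    di <- vapply(1:3, function(i) n_var(2L, 1L, 500 + 10 * s + i), numeric(1))
    tri <- vapply(1:3, function(i) n_var(3L, 6L, 600 + 10 * s + i), numeric(1))
    expect_gt(median(tri), median(di))
  }
})
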