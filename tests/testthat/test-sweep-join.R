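test_that("point overlap is start-inclusive and end-exclusive", {
  rg <- data.frame(chrom = "chr1", start = 5L, end = 10L, value = 1)
  atStart <- pointJoin(VariantSet("chr1", 6L), rg)   # point 5
  expect_equal(length(atStart), 1L)
  atEnd <- pointJoin(VariantSet("chr1", 11L), rg)    # point 10
  expect_equal(length(atEnd), 0L)
})

test_that("flanking windows are [max(0, p - w), p + w + 1)", {
  # point 100, w = 50 -> window [50, 151) overlaps [140, 160)
  vm <- windowJoin(VariantSet("chr1", 101L),
                   data.frame(chrom = "chr1", start = 140L, end = 160L), 50)
  expect_equal(length(vm), 1L)
  # but misses [151, 160)
  vm2 <- windowJoin(VariantSet("chr1", 101L),
                    data.frame(chrom = "chr1", start = 151L, end = 160L), 50)
  expect_equal(length(vm2), 0L)
  # clipped at zero: point 3, w = 10 -> window [0, 14)
  vm3 <- windowJoin(VariantSet("chr1", 4L),
                    data.frame(chrom = "chr1", start = 0L, end = 2L), 10)
  expect_equal(length(vm3), 1L)
})

test_that("coordinate ties follow the event priority of the half-open rule", {
  # a region ending at c never annotates a window starting at c
  vm <- windowJoin(VariantSet("chr1", 21L),  # point 20, w = 5: [15, 26)
                   data.frame(chrom = "chr1", start = 10L, end = 15L), 5)
  expect_equal(length(vm), 0L)
  # a region starting at c annotates a window ending just after c
  vm2 <- windowJoin(VariantSet("chr1", 21L),  # window [15, 26)
                    data.frame(chrom = "chr1", start = 25L, end = 30L), 5)
  expect_equal(length(vm2), 1L)
  # window end is exclusive: region starting exactly at p + w + 1 misses
  vm3 <- windowJoin(VariantSet("chr1", 21L),
                    data.frame(chrom = "chr1", start = 26L, end = 30L), 5)
  expect_equal(length(vm3), 0L)
})

test_that("w = 0 window join reduces exactly to the point join", {
  for (seed in 1:10) {
    inst <- randomInstance(seed)
    expect_identical(pairKey(windowJoin(inst$variants, inst$regions, 0)),
                     pairKey(pointJoin(inst$variants, inst$regions)))
  }
})

test_that("both sweeps agree with the brute-force oracle", {
  for (seed in 1:30) {
    inst <- randomInstance(seed)
    expect_identical(pairKey(pointJoin(inst$variants, inst$regions)),
                     pairKey(bruteForceJoin(inst$variants, inst$regions, 0)))
    for (w in c(10, 1000)) {
      expect_identical(
        pairKey(windowJoin(inst$variants, inst$regions, w)),
        pairKey(bruteForceJoin(inst$variants, inst$regions, w)))
    }
  }
})

test_that("sweeps agree with GenomicRanges::findOverlaps", {
  for (seed in c(2, 17)) {
    inst <- randomInstance(seed)
    gr <- GenomicRanges::GRanges(
      inst$regions$chrom,
      IRanges::IRanges(inst$regions$start + 1L, inst$regions$end))
    for (w in c(0, 250)) {
      vgr <- GenomicRanges::GRanges(
        variantChroms(inst$variants),
        IRanges::IRanges(pmax(0L, variantPoints(inst$variants) - w) + 1L,
                         variantPoints(inst$variants) + w + 1L))
      hits <- GenomicRanges::findOverlaps(vgr, gr)
      ref <- sort(paste(S4Vectors::queryHits(hits),
                        S4Vectors::subjectHits(hits), sep = ":"))
      got <- if (w == 0) pointJoin(inst$variants, inst$regions)
             else windowJoin(inst$variants, inst$regions, w)
      expect_identical(pairKey(got), ref)
    }
  }
})

test_that("pair sets grow monotonically with the flank", {
  inst <- randomInstance(11)
  k0 <- pairKey(windowJoin(inst$variants, inst$regions, 0))
  k10 <- pairKey(windowJoin(inst$variants, inst$regions, 10))
  k1000 <- pairKey(windowJoin(inst$variants, inst$regions, 1000))
  expect_true(all(k0 %in% k10))
  expect_true(all(k10 %in% k1000))
})

test_that("active-set counters certify the single-pass contract", {
  for (seed in 1:10) {
    inst <- randomInstance(seed)
    sp <- joinStats(pointJoin(inst$variants, inst$regions))
    expect_equal(sp$insertions, nrow(inst$regions))
    expect_equal(sp$removals, sp$insertions)
    sw <- joinStats(windowJoin(inst$variants, inst$regions, 100))
    expect_equal(sw$insertions, nrow(inst$regions) + length(inst$variants))
    expect_equal(sw$removals, sw$insertions)
  }
})

test_that("duplicate region records each contribute their own pair", {
  rg <- data.frame(chrom = "chr1", start = c(5L, 5L), end = c(10L, 10L),
                   value = c(1, 1))
  vm <- pointJoin(VariantSet("chr1", 7L), rg)
  expect_equal(length(vm), 2L)
})

test_that("nested regions close by identity, not FIFO order", {
  # outer region opens first but closes last; both must annotate correctly
  rg <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(100L, 20L),
                   value = c(1, 2))
  vs <- VariantSet("chr1", c(16L, 51L))  # points 15 (in both), 50 (outer only)
  p <- joinPairs(pointJoin(vs, rg))
  expect_equal(nrow(p), 3L)
  expect_equal(sort(p$start[p$variant == 1]), c(0L, 10L))
  expect_equal(p$start[p$variant == 2], 0L)
})

test_that("unsorted regions violate the scan precondition", {
  rg <- data.frame(chrom = "chr1", start = c(50L, 10L), end = c(60L, 20L))
  expect_error(pointJoin(VariantSet("chr1", 15L), rg), "unsorted")
})

test_that("the flank parameter is capped at 1 Mb", {
  vs <- VariantSet("chr1", 10L)
  rg <- data.frame(chrom = "chr1", start = 5L, end = 15L)
  expect_equal(length(windowJoin(vs, rg, 1e6)), 1L)
  expect_error(windowJoin(vs, rg, 1e6 + 1), class = "vs_param_error")
  expect_error(windowJoin(vs, rg, -1), class = "vs_param_error")
  expect_error(bruteForceJoin(vs, rg, 2e6), class = "vs_param_error")
})

test_that("chromosome naming conventions are normalized on both sides", {
  vm <- pointJoin(VariantSet("1", 8L),
                  data.frame(chrom = "chr1", start = 5L, end = 10L))
  expect_equal(length(vm), 1L)
  vm2 <- pointJoin(VariantSet("chr1", 8L),
                   data.frame(chrom = "1", start = 5L, end = 10L))
  expect_equal(length(vm2), 1L)
})
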