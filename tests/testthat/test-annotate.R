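test_that("mid-rank percentiles match the frozen worked examples", {
  expect_equal(percentileRank(40, c(10, 20, 30, 40)), 87.5)
  expect_equal(percentileRank(5, c(10, 20, 30, 40)), 0)
  expect_equal(percentileRank(50, 1:100), 49.5)
  expect_error(percentileRank(1, numeric()), class = "vs_param_error")
})

test_that("percentiles stay in [0, 100] and increase with the mean", {
  set.seed(99)
  dist <- valueDistributionFromValues(runif(200))
  q <- sort(runif(50, -0.5, 1.5))
  p <- percentileRank(q, dist)
  expect_true(all(p >= 0 & p <= 100))
  expect_true(all(diff(p) >= 0))
  # strictly increasing on a distribution with distinct values
  expect_true(all(diff(percentileRank(sort(slot(dist, "values")),
                                      dist)) > 0))
})

test_that("numeric summaries are unweighted means plus their percentile", {
  dist <- valueDistributionFromValues(c(1, 2, 3, 4))
  sm <- summarizeNumeric(c(2, 4), dist)
  expect_equal(unname(sm["mean"]), 3)
  expect_equal(unname(sm["percentile"]), percentileRank(3, dist))
  expect_equal(unname(summarizeNumeric(7.5,
    valueDistributionFromValues(7.5))["mean"]), 7.5)
  expect_error(summarizeNumeric(numeric(), dist), class = "vs_param_error")
})

test_that("annotation emits one record per overlapping (variant, feature)", {
  vs <- VariantSet("chr1", 101L)  # point 100
  sNum <- tmpStore(data.frame(chrom = "chr1", start = c(90L, 95L),
                              end = c(120L, 105L), value = c(2, 4)),
                   name = "signal")
  sCat <- tmpStore(data.frame(chrom = "chr1", start = 500L, end = 600L,
                              value = "enhancer"),
                   name = "state", type = "categorical")
  at <- runAnnotation(vs, list(sNum, sCat), window = 0,
                      jobId = strrep("0", 128))
  r <- slot(at, "records")
  expect_equal(nrow(r), 1L)
  expect_equal(r$feature, "signal")
  expect_equal(r$count, 2L)
  expect_equal(r$mean, 3)
  expect_equal(r$percentile, percentileRank(3, valueDistribution(sNum)))
})

test_that("every exact-location record persists when the window widens", {
  gm <- testGenome()
  vs <- simulateVariants(150, gm, 21)
  st <- tmpStore(simulateFeature(80, c(5, 60), c(0, 1), gm, 22))
  key <- function(at) {
    r <- slot(at, "records")
    paste(r$variantRow, r$feature)
  }
  k0 <- key(runAnnotation(vs, st, window = 0, jobId = strrep("0", 128)))
  k100 <- key(runAnnotation(vs, st, window = 100, jobId = strrep("0", 128)))
  expect_true(all(k0 %in% k100))
})

test_that("annotation counts match a brute-force recomputation end to end", {
  gm <- testGenome()
  vs <- simulateVariants(100, gm, 31)
  regions <- simulateFeature(60, c(5, 60), c(0, 1), gm, 32)
  st <- tmpStore(regions, name = "sig")
  for (w in c(0, 100)) {
    at <- runAnnotation(vs, st, window = w, jobId = strrep("0", 128))
    r <- slot(at, "records")
    bf <- joinPairs(bruteForceJoin(vs, regions, w))
    bfCount <- table(bf$variant)
    vrow <- inputOrder(vs)  # table rows are in input order
    expect_equal(nrow(r), length(bfCount))
    got <- setNames(r$count, r$variantRow)
    want <- setNames(as.integer(bfCount), vrow[as.integer(names(bfCount))])
    expect_equal(got[order(as.integer(names(got)))],
                 want[order(as.integer(names(want)))])
  }
})

test_that("variants keep input order and zero-overlap rows render blank", {
  vs <- parseVariants(c("chr2 50", "chr1 101"))  # input order chr2 first
  st <- tmpStore(data.frame(chrom = "chr1", start = 90L, end = 120L,
                            value = 5), name = "sig")
  at <- runAnnotation(vs, st, window = 0, jobId = strrep("0", 128))
  v <- slot(at, "variants")
  expect_equal(v$chrom, c("chr2", "chr1"))
  out <- tempfile(fileext = ".tsv")
  writeTable(at, out)
  lines <- readLines(out)
  expect_equal(length(lines), 3L)  # header + both variants
  parsed <- utils::read.delim(out, colClasses = "character",
                              check.names = FALSE)
  expect_equal(parsed$chrom, c("chr2", "chr1"))
  expect_equal(parsed[["sig.count"]], c("", "1"))  # blank = no overlap
  expect_equal(parsed[["sig.value"]], c("", "5"))
})

test_that("written tables re-parse to identical cells and are deterministic", {
  gm <- testGenome()
  vs <- simulateVariants(40, gm, 51)
  st1 <- tmpStore(simulateFeature(30, c(5, 50), c(0, 1), gm, 52),
                  name = "sig")
  st2 <- tmpStore(simulateFeature(10, c(5, 50), c("a", "b"), gm, 53),
                  name = "lab", type = "categorical")
  at <- runAnnotation(vs, list(st1, st2), window = 50,
                      jobId = strrep("0", 128))
  f1 <- tempfile(); f2 <- tempfile()
  writeTable(at, f1); writeTable(at, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  parsed <- utils::read.delim(f1, colClasses = "character", check.names = FALSE)
  expect_equal(nrow(parsed), 40L)
  expect_equal(names(parsed)[1:5], c("chrom", "pos", "ref", "alt", "kind"))
  expect_equal(names(parsed)[6:8],
               c("sig.count", "sig.value", "sig.percentile"))
  # numeric cells survive the round trip exactly
  r <- slot(at, "records")
  numRec <- r[r$feature == "sig", ][1, ]
  expect_equal(as.numeric(parsed[numRec$variantRow, "sig.value"]),
               numRec$mean)
})

test_that("a header-only table is written when nothing is annotated", {
  vs <- VariantSet("chr9", 10L)
  st <- tmpStore(data.frame(chrom = "chr1", start = 1L, end = 5L, value = 1))
  expect_warning(at <- runAnnotation(vs, st, jobId = strrep("0", 128)),
                 "share no chromosome")
  out <- tempfile()
  writeTable(at, out)
  expect_equal(length(readLines(out)), 2L)  # header + the blank variant row
})

test_that("unique-locus accounting collapses the published example to 21", {
  pgp <- pgpExampleVariants()
  expect_equal(length(pgp$variants), 31L)
  dd <- dedupUniqueLoci(pgp$variants)
  expect_equal(dd$count, 21L)
  expect_equal(length(dd$variants), 21L)
  expect_equal(dedupUniqueLoci(VariantSet(character(), integer()))$count, 0L)
  expect_equal(dedupUniqueLoci(VariantSet(c("chr1", "chr1"),
                                          c(5L, 5L)))$count, 1L)
})

test_that("job identifiers are 512 random hex bits", {
  id <- generateJobId()
  expect_match(id, "^[0-9a-f]{128}$")
  expect_false(generateJobId() == generateJobId())
})

test_that("the window cap is enforced at configuration time", {
  ok <- jobConfig(1e6, "store.vasf")
  expect_s4_class(ok, "JobConfig")
  expect_error(jobConfig(1e6 + 1, "store.vasf"), class = "vs_config_error")
  expect_error(jobConfig(-5, "store.vasf"), class = "vs_config_error")
  expect_error(jobConfig(100, character()), class = "vs_config_error")
})

test_that("spreadsheet output is declined with a clear configuration error", {
  vs <- VariantSet("chr1", 10L)
  st <- tmpStore(data.frame(chrom = "chr1", start = 5L, end = 15L,
                            value = 1))
  at <- runAnnotation(vs, st, jobId = strrep("0", 128))
  expect_error(writeTable(at, tempfile(), format = "spreadsheet"),
               class = "vs_config_error")
})
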