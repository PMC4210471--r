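test_that("BED import honors the value column and default labels", {
  r <- importBed("chr1\t10\t20\tpeak1\t7.5", valueColumn = 5)
  expect_equal(r$value, 7.5)
  expect_equal(r[, c("start", "end")], data.frame(start = 10L, end = 20L))
  # no value column: the name column becomes a label
  r2 <- importBed("chr1\t10\t20\tpeak1")
  expect_equal(r2$value, "peak1")
  # 3-column records get the constant label
  expect_equal(importBed("chr1\t10\t20")$value, "present")
})

test_that("BED import rejects bad records with their line number", {
  expect_error(importBed(c("chr1\t10\t20", "chr1\t20\t10")),
               "line 2", class = "vs_record_error")
  expect_error(importBed("chr1\t10\t10"), class = "vs_record_error")
  expect_error(importBed("chr1\t10\t20\tx", valueColumn = 4),
               class = "vs_record_error")
  expect_error(importBed("chr1\t10"), class = "vs_format_error")
})

test_that("BED import skips headers and matches rtracklayer on plain BED", {
  skip_if_not_installed("rtracklayer")
  lines <- c("track name=demo", "# comment",
             "chr1\t100\t200\tp1\t5", "chr2\t0\t50\tp2\t7")
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  mine <- importBed(path, valueColumn = 5)
  ref <- as.data.frame(rtracklayer::import(path))
  expect_equal(mine$start, ref$start - 1L)  # rtracklayer is 1-based
  expect_equal(mine$end, ref$end)
  expect_equal(mine$value, ref$score)
  expect_equal(mine$chrom, as.character(ref$seqnames))
})

test_that("stores sort regions and build a consistent directory", {
  st <- tmpStore(data.frame(chrom = c("chr1", "chr2", "chr1"),
                            start = c(50L, 5L, 10L), end = c(60L, 9L, 20L),
                            value = c(1, 2, 3)))
  sc <- scanRegions(st, "chr1")
  expect_equal(sc$start, c(10L, 50L))
  expect_equal(sc$value, c(3, 1))
  d <- storeDirectory(st)
  expect_equal(sum(d$count), nRegions(st))
  # offsets advance by exactly 12 bytes per record
  expect_equal(diff(d$offset), 12 * head(d$count, -1))
})

test_that("seek-scan equals the full scan filtered to the chromosome", {
  gm <- genomeModel(c("chr1", "chr2", "chr3"), c(5000, 3000, 2000))
  for (seed in 1:50) {
    regions <- simulateFeature(40, c(1, 50), c(0, 10), gm, seed)
    st <- tmpStore(regions)
    full <- do.call(rbind, lapply(storeDirectory(st)$chrom, scanRegions,
                                  store = st))
    for (ch in storeDirectory(st)$chrom) {
      sc <- scanRegions(st, ch)
      expect_equal(sc, full[full$chrom == ch, ], ignore_attr = TRUE)
    }
  }
})

test_that("scans start at the directory pointer and read only that chromosome", {
  st <- tmpStore(data.frame(chrom = rep(c("chr1", "chr2"), c(100, 7)),
                            start = 0:106 * 10L, end = 0:106 * 10L + 5L,
                            value = 1))
  d <- storeDirectory(st)
  sc <- scanRegions(st, "chr2")
  expect_equal(attr(sc, "offsetUsed"), d$offset[d$chrom == "chr2"])
  expect_equal(attr(sc, "recordsRead"), 7)
  expect_equal(nrow(sc), 7L)
})

test_that("absent chromosomes yield an empty stream, not an error", {
  st <- tmpStore(data.frame(chrom = "chr1", start = 1L, end = 2L, value = 1))
  expect_equal(nrow(scanRegions(st, "chrZ")), 0L)
})

test_that("stores round-trip the region multiset, duplicates included", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                        start = c(5L, 5L, 30L), end = c(9L, 9L, 35L),
                        value = c(1.5, 1.5, 2.25))
  st <- tmpStore(regions)
  sc <- scanRegions(st, "chr1")
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$value, c(1.5, 1.5, 2.25))
})

test_that("reopening a store reproduces directory and values", {
  regions <- simulateFeature(30, c(1, 20), c(0, 4), testGenome(), 5)
  path <- tempfile(fileext = ".vasf")
  built <- buildFeatureStore(regions, "track", "numeric", path)
  reopened <- openFeatureStore(path)
  expect_equal(storeDirectory(reopened), storeDirectory(built))
  expect_equal(slot(reopened, "sortedValues"), slot(built, "sortedValues"))
  expect_equal(featureName(reopened), "track")
})

test_that("the value distribution equals a naive sort of all region values", {
  vals <- c(3, 1, 2, 2, 10) / 4  # exactly representable as f32
  st <- tmpStore(data.frame(chrom = "chr1", start = 1:5 * 10L,
                            end = 1:5 * 10L + 4L, value = vals))
  dist <- valueDistribution(st)
  expect_equal(slot(dist, "n"), 5)
  expect_equal(slot(dist, "values"), sort(vals))
  # any quantile query agrees with the naive computation
  expect_equal(percentileRank(0.5, dist), percentileRank(0.5, sort(vals)))
})

test_that("categorical stores refuse numeric-only operations", {
  st <- tmpStore(data.frame(chrom = "chr1", start = 1L, end = 5L,
                            value = "enhancer"), type = "categorical")
  expect_error(valueDistribution(st), class = "vs_type_error")
  expect_equal(scanRegions(st, "chr1")$value, "enhancer")
})

test_that("mixed or invalid values are rejected at build time", {
  expect_error(tmpStore(data.frame(chrom = "chr1", start = 1L, end = 5L,
                                   value = "high"), type = "numeric"),
               class = "vs_type_error")
  expect_error(tmpStore(data.frame(chrom = "chr1", start = 30L, end = 30L,
                                   value = 1)),
               class = "vs_record_error")
})

test_that("an empty region sequence builds a valid empty store", {
  st <- tmpStore(data.frame(chrom = character(), start = integer(),
                            end = integer(), value = numeric()))
  expect_equal(nRegions(st), 0)
  expect_equal(nrow(scanRegions(st, "chr1")), 0L)
})
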