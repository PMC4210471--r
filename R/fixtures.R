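## Seeded synthetic-data generators: genome models, uniform variant lists
## and feature tracks, and planted-truth join instances with known answers.

#' Construct a genome model
#'
#' @param chromNames unique chromosome names.
#' @param chromLengths positive lengths in bp.
#' @return a [GenomeModel-class].
#' @export
genomeModel <- function(chromNames, chromLengths) {
  new("GenomeModel", chromNames = as.character(chromNames),
      chromLengths = as.numeric(chromLengths))
}

#' Human-scale genome model (hg19 chromosome lengths)
#'
#' The 24 nuclear chromosomes of the hg19 assembly, ~3.1 Gb in total.
#' Used for size and scaling experiments where coordinate magnitudes
#' matter (varints grow with the coordinates and with the inter-variant
#' gaps).
#'
#' @return a [GenomeModel-class] with 24 chromosomes.
#' @export
hg19GenomeModel <- function() {
  genomeModel(
    c(paste0("chr", 1:22), "chrX", "chrY"),
    c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566, 155270560, 59373566))
}

#' Tiny two-chromosome genome for logic tests
#'
#' @return a [GenomeModel-class] with chromosomes chrA (10 kb) and
#'   chrB (5 kb).
#' @export
toyGenomeModel <- function() {
  genomeModel(c("chrA", "chrB"), c(10000, 5000))
}

#' Simulate a uniform variant list
#'
#' Draws \code{n} point-only variants uniformly over the genome:
#' chromosomes are chosen with probability proportional to their length
#' and positions uniformly within the chromosome. Reproducible for a
#' fixed seed.
#'
#' @param n number of variants (>= 0).
#' @param gm a [GenomeModel-class].
#' @param seed integer seed.
#' @return a [VariantSet-class].
#' @export
simulateVariants <- function(n, gm, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    vsError("n must be a non-negative count", "vs_param_error")
  n <- as.integer(n)
  withr::with_seed(seed, {
    ci <- sample.int(length(gm@chromNames), n, replace = TRUE,
                     prob = gm@chromLengths)
    pos <- floor(runif(n) * gm@chromLengths[ci]) + 1
  })
  VariantSet(gm@chromNames[ci], pos)
}

#' Simulate a feature track
#'
#' Generates regions with uniformly drawn lengths and values, placed
#' uniformly (chromosomes proportional to length), clipped to chromosome
#' bounds. Regions may overlap and nest. Reproducible for a fixed seed.
#'
#' @param nRegions number of regions (>= 0).
#' @param lengthLaw numeric \code{c(min, max)} region length in bp,
#'   \code{min >= 1}.
#' @param valueLaw either numeric \code{c(lo, hi)} for uniform signal
#'   values or a character vector of labels to sample from.
#' @param gm a [GenomeModel-class].
#' @param seed integer seed.
#' @return data.frame with columns chrom, start, end, value, sorted by
#'   (chrom, start, end).
#' @export
simulateFeature <- function(nRegions, lengthLaw, valueLaw, gm, seed) {
  if (!is.numeric(nRegions) || length(nRegions) != 1L || is.na(nRegions) ||
      nRegions < 0)
    vsError("nRegions must be a non-negative count", "vs_param_error")
  if (!is.numeric(lengthLaw) || length(lengthLaw) != 2L ||
      lengthLaw[1] < 1 || lengthLaw[2] < lengthLaw[1])
    vsError("lengthLaw must be c(min, max) with min >= 1", "vs_param_error")
  numericValues <- is.numeric(valueLaw)
  if (numericValues && (length(valueLaw) != 2L || valueLaw[2] < valueLaw[1]))
    vsError("numeric valueLaw must be c(lo, hi)", "vs_param_error")
  if (!numericValues && (!is.character(valueLaw) || !length(valueLaw)))
    vsError("categorical valueLaw must be a non-empty label set",
            "vs_param_error")
  nRegions <- as.integer(nRegions)
  withr::with_seed(seed, {
    ci <- sample.int(length(gm@chromNames), nRegions, replace = TRUE,
                     prob = gm@chromLengths)
    len <- floor(runif(nRegions, lengthLaw[1], lengthLaw[2] + 1))
    start <- floor(runif(nRegions) * pmax(1, gm@chromLengths[ci] - len))
    end <- pmin(start + len, gm@chromLengths[ci])
    value <- if (numericValues) runif(nRegions, valueLaw[1], valueLaw[2])
             else sample(valueLaw, nRegions, replace = TRUE)
  })
  out <- data.frame(chrom = gm@chromNames[ci], start = as.integer(start),
                    end = as.integer(end), value = value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a planted-truth join instance
#'
#' Lays out non-interacting slots across the genome. Each slot holds one
#' variant and one region: in \code{kOverlaps} slots the region is placed
#' inside the variant's flanking window (guaranteed overlap under
#' \code{w}); in \code{kNonoverlaps} slots the region is separated from
#' the variant by more than \code{w} plus the maximum region length
#' (guaranteed non-overlap). Slot spacing also guarantees that windows
#' never reach a neighboring slot, so the expected pair set is exactly
#' the planted overlaps — which by construction equals
#' [bruteForceJoin()]'s answer.
#'
#' @param kOverlaps,kNonoverlaps slot counts (>= 0).
#' @param w flank in bp per side (0 to 1e6).
#' @param gm a [GenomeModel-class]; a construction error is raised when
#'   the genome cannot hold the requested slots at the required
#'   separation.
#' @param seed integer seed.
#' @param maxRegionLen maximum region length in bp.
#' @return list with elements \code{variants} ([VariantSet-class]),
#'   \code{regions} (sorted data.frame), \code{expected} (data.frame of
#'   the planted (chrom, point, start, end) pairs) and \code{w}.
#' @export
plantedInstance <- function(kOverlaps, kNonoverlaps, w, gm, seed,
                            maxRegionLen = 50) {
  if (kOverlaps < 0 || kNonoverlaps < 0)
    vsError("slot counts must be non-negative", "vs_param_error")
  w <- checkFlank(w)
  k <- kOverlaps + kNonoverlaps
  stride <- 2 * w + 4 * maxRegionLen + 16
  # sequential slot allocation across chromosomes
  perChrom <- floor(gm@chromLengths / stride)
  if (sum(perChrom) < k)
    vsError(sprintf(
      "genome too small: %d slots of %d bp needed, %d available",
      k, stride, sum(perChrom)), "vs_construction_error")
  chromIdx <- rep(seq_along(gm@chromNames), perChrom)[seq_len(k)]
  slotRank <- sequence(pmin(perChrom, tabulate(chromIdx,
                       nbins = length(gm@chromNames))))[seq_len(k)]
  base <- (slotRank - 1) * stride

  withr::with_seed(seed, {
    isOverlap <- sample(rep(c(TRUE, FALSE), c(kOverlaps, kNonoverlaps)))
    p <- base + w + maxRegionLen + 4  # variant point, 0-based
    len <- floor(runif(k, 1, maxRegionLen + 1))
    off <- floor(runif(k, -w, w + 1))  # region start offset within window
    rs <- ifelse(isOverlap, p + off, p + w + maxRegionLen + 4)
    val <- runif(k)
  })
  re <- rs + len
  chrom <- gm@chromNames[chromIdx]

  variants <- VariantSet(chrom, p + 1)
  regions <- data.frame(chrom = chrom, start = as.integer(rs),
                        end = as.integer(re), value = val,
                        stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start, regions$end,
                           method = "radix"), , drop = FALSE]
  rownames(regions) <- NULL
  expected <- data.frame(chrom = chrom[isOverlap],
                         point = as.integer(p[isOverlap]),
                         start = as.integer(rs[isOverlap]),
                         end = as.integer(re[isOverlap]))
  expected <- expected[order(expected$chrom, expected$point,
                             method = "radix"), , drop = FALSE]
  rownames(expected) <- NULL
  list(variants = variants, regions = regions, expected = expected, w = w)
}

#' Published personal-genome variant loci bundled with the package
#'
#' A transcription of 31 clinically reported variant rows (five personal
#' genomes; likely pathogenic and rare pathogenic variants) used as a
#' worked example: several loci recur across samples, so the 31 rows
#' collapse to 21 unique (chromosome, position) loci. Positions are the
#' first printed (hg19) coordinate of each row.
#'
#' @return list with elements \code{table} (the raw data.frame: sample,
#'   label, chrom, pos, dbsnp, importance) and \code{variants} (a
#'   [VariantSet-class] of the 31 loci, duplicates retained).
#' @export
pgpExampleVariants <- function() {
  path <- system.file("extdata", "pgp_table4_variants.tsv",
                      package = "VariantSweep", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(table = tab, variants = VariantSet(tab$chrom, tab$pos))
}

## ---- text emitters so fixtures can exercise the real parsers -------------

#' Write fixtures as standard text formats
#'
#' \code{writeVariantsVcf} writes a minimal VCF (CHROM POS ID REF ALT
#' QUAL FILTER INFO); \code{writeVariantsList} a whitespace-delimited
#' chrom/position list; \code{writeRegionsBed} BED text, with the value
#' in column 4 (bedGraph-like for numeric values). Rows are written in
#' input order for variant sets.
#'
#' @param x a [VariantSet-class] or region data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @name fixtureWriters
NULL

#' @rdname fixtureWriters
#' @export
writeVariantsVcf <- function(x, path) {
  d <- as.data.frame(x)
  d <- d[order(d$inputIndex), , drop = FALSE]
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", d$chrom, d$pos,
                     ifelse(d$ref == "", "N", d$ref),
                     ifelse(d$alt == "", ".", d$alt)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname fixtureWriters
#' @export
writeVariantsList <- function(x, path) {
  d <- as.data.frame(x)
  d <- d[order(d$inputIndex), , drop = FALSE]
  writeLines(sprintf("%s %d", d$chrom, d$pos), path)
  invisible(path)
}

#' @rdname fixtureWriters
#' @export
writeRegionsBed <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), as.character(x$value)), path)
  invisible(path)
}
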