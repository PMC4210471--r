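#' GenomeModel: chromosome names and lengths
#'
#' A minimal genome description used by the synthetic-data generators and
#' for clipping simulated regions. Chromosome names are unique and lengths
#' strictly positive.
#'
#' @slot chromNames character vector of unique chromosome names.
#' @slot chromLengths numeric vector of positive lengths (bp), parallel to
#'   \code{chromNames}.
#' @seealso [genomeModel()], [hg19GenomeModel()], [toyGenomeModel()]
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(chromNames = "character", chromLengths = "numeric"))

setValidity("GenomeModel", function(object) {
  if (length(object@chromNames) != length(object@chromLengths))
    return("chromNames and chromLengths must have equal length")
  if (anyDuplicated(object@chromNames))
    return("chromosome names must be unique")
  if (any(!is.finite(object@chromLengths)) || any(object@chromLengths < 1))
    return("chromosome lengths must be positive")
  TRUE
})

#' VariantSet: a sorted list of genetic variants
#'
#' Variants are stored per chromosome, sorted in non-decreasing order of
#' their representative point (0-based). The representative point is the
#' exact location for an SNV, an insertion or a point-only record, and the
#' floor mid-point of the deleted span for a deletion; it is always equal
#' to [representativePoint()] recomputed from the record. The original
#' input order is retained in \code{inputIndex} so reports can present
#' variants as the user listed them.
#'
#' @slot chrom character, normalized ("chr"-prefixed) chromosome names.
#' @slot pos integer, 1-based positions as parsed.
#' @slot ref,alt character alleles; both empty for point-only records.
#' @slot kind character, one of "SNV", "insertion", "deletion", "point".
#' @slot point integer, 0-based representative coordinate.
#' @slot inputIndex integer, 1-based rank of each record in the input.
#' @seealso [parseVariants()], [compressVariants()], [simulateVariants()]
#' @exportClass VariantSet
setClass("VariantSet",
  representation(chrom = "character", pos = "integer", ref = "character",
                 alt = "character", kind = "character", point = "integer",
                 inputIndex = "integer"))

setValidity("VariantSet", function(object) {
  n <- length(object@chrom)
  lens <- c(length(object@pos), length(object@ref), length(object@alt),
            length(object@kind), length(object@point),
            length(object@inputIndex))
  if (any(lens != n)) return("all slots must have equal length")
  if (n == 0L) return(TRUE)
  if (any(object@pos < 1L)) return("positions must be >= 1")
  if (!all(object@kind %in% c("SNV", "insertion", "deletion", "point")))
    return("unknown variant kind")
  ptOnly <- object@ref == "" & object@alt == ""
  if (!identical(unname(object@kind == "point"), unname(ptOnly)))
    return("kind 'point' iff ref and alt are both empty")
  expect <- representativePoint(object@pos, object@ref, object@alt,
                                object@kind)
  if (!identical(unname(as.integer(expect)), unname(object@point)))
    return("stored points disagree with representativePoint()")
  bad <- vapply(split(object@point, object@chrom),
                function(p) is.unsorted(p), logical(1))
  if (any(bad)) return("points must be non-decreasing within chromosome")
  TRUE
})

#' CompressedVariants: the compact transfer payload
#'
#' Binary encoding of a [VariantSet]'s locations: per chromosome, the first
#' 0-based point absolute and subsequent points delta-encoded as unsigned
#' LEB128 varints. Layout (little-endian): magic "VASC", version u8 = 1,
#' u32 chromosome count, then per chromosome u8 name length, name bytes,
#' u64 count, count varints. Only locations are kept — alleles, genotypes
#' and all other columns are dropped.
#'
#' @slot payload raw vector, the encoded bytes.
#' @slot directory data.frame with columns \code{chrom}, \code{count},
#'   \code{offset} (0-based byte offset of each chromosome block).
#' @seealso [compressVariants()], [decompressVariants()]
#' @exportClass CompressedVariants
setClass("CompressedVariants",
  representation(payload = "raw", directory = "data.frame"))

setValidity("CompressedVariants", function(object) {
  d <- object@directory
  if (!all(c("chrom", "count", "offset") %in% names(d)))
    return("directory must have chrom, count, offset columns")
  if (length(object@payload) < 9L)
    return("payload shorter than the fixed header")
  TRUE
})

#' FeatureStore: a sorted on-disk genomic feature track
#'
#' A feature track persisted in a seekable binary file: regions sorted by
#' (start, end) within each chromosome, a pointer directory mapping each
#' chromosome name to the byte offset of its first record (so a scan can
#' start there directly, without reading preceding chromosomes), and — for
#' numeric tracks — a footer holding the sorted array of all region values
#' used for percentile reporting. Overlapping and nested regions are
#' preserved as imported, never merged.
#'
#' @slot path character, the backing file.
#' @slot featureName character, display name of the track.
#' @slot valueType "numeric" or "categorical".
#' @slot directory data.frame with columns \code{chrom}, \code{offset}
#'   (absolute file offset of the first record), \code{count}.
#' @slot nRegions numeric, total record count.
#' @slot stringTable character, labels for categorical stores.
#' @slot sortedValues numeric, sorted region values (numeric stores).
#' @seealso [buildFeatureStore()], [openFeatureStore()], [scanRegions()]
#' @exportClass FeatureStore
setClass("FeatureStore",
  representation(path = "character", featureName = "character",
                 valueType = "character", directory = "data.frame",
                 nRegions = "numeric", stringTable = "character",
                 sortedValues = "numeric"))

setValidity("FeatureStore", function(object) {
  if (!object@valueType %in% c("numeric", "categorical"))
    return("valueType must be 'numeric' or 'categorical'")
  if (sum(object@directory$count) != object@nRegions)
    return("directory counts must sum to the total record count")
  if (object@valueType == "numeric" &&
      length(object@sortedValues) != object@nRegions)
    return("numeric store must carry one sorted value per record")
  TRUE
})

#' ValueDistribution: genome-wide distribution of a numeric feature
#'
#' The exact sorted multiset of all region values of a numeric
#' [FeatureStore], used to place a variant's window mean among all genomic
#' regions via the mid-rank percentile.
#'
#' @slot n numeric, number of values (equals the store's record count).
#' @slot values numeric, sorted ascending.
#' @seealso [valueDistribution()], [percentileRank()]
#' @exportClass ValueDistribution
setClass("ValueDistribution",
  representation(n = "numeric", values = "numeric"))

setValidity("ValueDistribution", function(object) {
  if (object@n != length(object@values))
    return("n must equal length(values)")
  if (is.unsorted(object@values)) return("values must be sorted")
  TRUE
})

#' VariantMap: the result of a sweep join
#'
#' Maps variants to the feature regions that annotate them. Each
#' (variant, region) pair appears at most once. Pairs reference variants by
#' their index in the sorted [VariantSet] and carry the region coordinates
#' and value. Instrumentation from the sweep (active-set insertion and
#' removal counters) is kept in \code{stats}; a single linear pass inserts
#' each region (and, for window joins, each variant) into its active set
#' exactly once.
#'
#' @slot pairs data.frame with columns \code{variant} (index into the
#'   sorted variant set), \code{region} (index into the region
#'   data.frame), \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @slot stats list with elements \code{insertions}, \code{removals},
#'   \code{nVariants}, \code{nRegions}.
#' @seealso [pointJoin()], [windowJoin()], [bruteForceJoin()]
#' @exportClass VariantMap
setClass("VariantMap",
  representation(pairs = "data.frame", stats = "list"))

setValidity("VariantMap", function(object) {
  p <- object@pairs
  need <- c("variant", "region", "chrom", "start", "end")
  if (!all(need %in% names(p)))
    return("pairs must have variant, region, chrom, start, end columns")
  if (anyDuplicated(paste(p$variant, p$region)))
    return("each (variant, region) pair may appear at most once")
  TRUE
})

#' JobConfig: parameters of one annotation job
#'
#' @slot window numeric flank size in bp, per side; 0 requests
#'   exact-location integration, values up to 1e6 (1 Mb) request
#'   flanking-window integration.
#' @slot storePaths character, at least one feature store file.
#' @slot outputPath character, where the TSV report goes.
#' @slot jobId character, 128 lowercase hex characters (512 bits).
#' @seealso [jobConfig()], [runAnnotation()], [generateJobId()]
#' @exportClass JobConfig
setClass("JobConfig",
  representation(window = "numeric", storePaths = "character",
                 outputPath = "character", jobId = "character"))

setValidity("JobConfig", function(object) {
  if (length(object@window) != 1L || is.na(object@window) ||
      object@window < 0 || object@window > 1e6)
    return("window must be a single value in [0, 1000000] bp")
  if (length(object@storePaths) < 1L)
    return("at least one feature store must be selected")
  TRUE
})

#' AnnotationTable: the per-variant, per-feature report
#'
#' One record per (variant, feature) pair with at least one overlapping
#' region; variants with no overlaps in any feature still appear in the
#' written table as a row of blanks. Row order follows the input variant
#' order and column groups follow the feature selection order.
#'
#' @slot variants data.frame of the input variants in input order
#'   (chrom, pos, ref, alt, kind, point).
#' @slot features character, feature names in selection order.
#' @slot records data.frame with columns \code{variantRow} (row in
#'   \code{variants}), \code{feature}, \code{count}, \code{labels},
#'   \code{mean}, \code{percentile}.
#' @slot window numeric, the flank used.
#' @slot jobId character job identifier.
#' @seealso [runAnnotation()], [writeTable()]
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  representation(variants = "data.frame", features = "character",
                 records = "data.frame", window = "numeric",
                 jobId = "character"))

setValidity("AnnotationTable", function(object) {
  r <- object@records
  need <- c("variantRow", "feature", "count", "labels", "mean", "percentile")
  if (!all(need %in% names(r)))
    return("records is missing required columns")
  if (nrow(r)) {
    if (any(r$count < 1L))
      return("emitted records must have at least one overlapping region")
    pc <- r$percentile[!is.na(r$percentile)]
    if (any(pc < 0 | pc > 100)) return("percentiles must lie in [0, 100]")
    if (!all(r$feature %in% object@features))
      return("records reference unknown features")
    if (any(r$variantRow < 1L | r$variantRow > nrow(object@variants)))
      return("records reference unknown variants")
  }
  TRUE
})
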