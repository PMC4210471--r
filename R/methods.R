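## Accessors, show methods and coercions.

#' @rdname GenomeModel-class
#' @export
setMethod("chromNames", "GenomeModel", function(x) x@chromNames)

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(x) {
  stats::setNames(x@chromLengths, x@chromNames)
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel with %d chromosomes, %.3g bp total\n",
              length(object@chromNames), sum(object@chromLengths)))
})

#' @rdname VariantSet-class
#' @export
setMethod("variantChroms", "VariantSet", function(x) x@chrom)

#' @rdname VariantSet-class
#' @export
setMethod("variantPoints", "VariantSet", function(x) x@point)

#' @rdname VariantSet-class
#' @export
setMethod("variantKinds", "VariantSet", function(x) x@kind)

#' @rdname VariantSet-class
#' @export
setMethod("inputOrder", "VariantSet", function(x) x@inputIndex)

#' @rdname VariantSet-class
#' @export
setMethod("length", "VariantSet", function(x) length(x@chrom))

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet with %d variants on %d chromosome(s)\n",
              length(object), length(unique(object@chrom))))
  if (length(object)) {
    tab <- table(object@kind)
    cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname VariantSet-class
#' @param row.names,optional,... passed on as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "VariantSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
               kind = x@kind, point = x@point, inputIndex = x@inputIndex,
               stringsAsFactors = FALSE)
  })

setAs("VariantSet", "GRanges", function(from) {
  gr <- GenomicRanges::GRanges(
    seqnames = from@chrom,
    ranges = IRanges::IRanges(start = from@point + 1L, width = 1L))
  S4Vectors::mcols(gr)$kind <- from@kind
  S4Vectors::mcols(gr)$inputIndex <- from@inputIndex
  gr
})

#' @rdname CompressedVariants-class
#' @export
setMethod("payloadBytes", "CompressedVariants", function(x) {
  length(x@payload)
})

setMethod("show", "CompressedVariants", function(object) {
  cat(sprintf(
    "CompressedVariants: %d variants on %d chromosome(s), %d bytes\n",
    sum(object@directory$count), nrow(object@directory),
    length(object@payload)))
})

#' @rdname FeatureStore-class
#' @export
setMethod("featureName", "FeatureStore", function(x) x@featureName)

#' @rdname FeatureStore-class
#' @export
setMethod("valueType", "FeatureStore", function(x) x@valueType)

#' @rdname FeatureStore-class
#' @export
setMethod("storeDirectory", "FeatureStore", function(x) x@directory)

#' @rdname FeatureStore-class
#' @export
setMethod("nRegions", "FeatureStore", function(x) x@nRegions)

setMethod("show", "FeatureStore", function(object) {
  cat(sprintf(
    "FeatureStore '%s' (%s): %d regions on %d chromosome(s)\n  file: %s\n",
    object@featureName, object@valueType, object@nRegions,
    nrow(object@directory), object@path))
})

setMethod("show", "ValueDistribution", function(object) {
  cat(sprintf("ValueDistribution over %d region values\n", object@n))
})

#' @rdname VariantMap-class
#' @export
setMethod("joinPairs", "VariantMap", function(x) x@pairs)

#' @rdname VariantMap-class
#' @export
setMethod("joinStats", "VariantMap", function(x) x@stats)

#' @rdname VariantMap-class
#' @export
setMethod("length", "VariantMap", function(x) nrow(x@pairs))

setMethod("show", "VariantMap", function(object) {
  cat(sprintf("VariantMap with %d (variant, region) pairs over %d variants\n",
              nrow(object@pairs), length(unique(object@pairs$variant))))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf(
    "AnnotationTable: %d variants x %d feature(s), %d annotated pairs (w = %g bp)\n",
    nrow(object@variants), length(object@features), nrow(object@records),
    object@window))
})

setMethod("show", "JobConfig", function(object) {
  cat(sprintf("JobConfig: window %g bp, %d store(s), job %s...\n",
              object@window, length(object@storePaths),
              substr(object@jobId, 1, 12)))
})
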