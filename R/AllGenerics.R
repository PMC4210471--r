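#' @rdname GenomeModel-class
#' @param x,object an object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeModel-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantChroms", function(x) standardGeneric("variantChroms"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantPoints", function(x) standardGeneric("variantPoints"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantKinds", function(x) standardGeneric("variantKinds"))

#' @rdname VariantSet-class
#' @export
setGeneric("inputOrder", function(x) standardGeneric("inputOrder"))

#' @rdname compressVariants
#' @export
setGeneric("compressVariants", function(x) standardGeneric("compressVariants"))

#' @rdname compressVariants
#' @export
setGeneric("decompressVariants",
           function(x) standardGeneric("decompressVariants"))

#' @rdname CompressedVariants-class
#' @export
setGeneric("payloadBytes", function(x) standardGeneric("payloadBytes"))

#' @rdname FeatureStore-class
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname FeatureStore-class
#' @export
setGeneric("valueType", function(x) standardGeneric("valueType"))

#' @rdname FeatureStore-class
#' @export
setGeneric("storeDirectory", function(x) standardGeneric("storeDirectory"))

#' @rdname FeatureStore-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname scanRegions
#' @param store a [FeatureStore].
#' @param chrom a single chromosome name.
#' @export
setGeneric("scanRegions",
           function(store, chrom) standardGeneric("scanRegions"))

#' @rdname valueDistribution
#' @export
setGeneric("valueDistribution",
           function(store) standardGeneric("valueDistribution"))

#' @rdname sweepJoins
#' @export
setGeneric("pointJoin",
           function(variants, regions) standardGeneric("pointJoin"))

#' @rdname sweepJoins
#' @export
setGeneric("windowJoin",
           function(variants, regions, w) standardGeneric("windowJoin"))

#' @rdname sweepJoins
#' @export
setGeneric("bruteForceJoin",
           function(variants, regions, w = 0) standardGeneric("bruteForceJoin"))

#' @rdname VariantMap-class
#' @export
setGeneric("joinPairs", function(x) standardGeneric("joinPairs"))

#' @rdname VariantMap-class
#' @export
setGeneric("joinStats", function(x) standardGeneric("joinStats"))

#' @rdname dedupUniqueLoci
#' @export
setGeneric("dedupUniqueLoci",
           function(x) standardGeneric("dedupUniqueLoci"))

#' @rdname runAnnotation
#' @export
setGeneric("runAnnotation",
           function(variants, stores, window = 0,
                    jobId = generateJobId())
             standardGeneric("runAnnotation"))

#' @rdname writeTable
#' @export
setGeneric("writeTable",
           function(x, path, format = c("tsv", "spreadsheet"))
             standardGeneric("writeTable"))
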