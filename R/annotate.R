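## Orchestration: join variants against many feature stores, summarize
## numeric signals, and write the tab-delimited report.

#' Mid-rank percentile of a value within a distribution
#'
#' Places \code{m} among all region values of a feature using the
#' mid-rank rule \code{p = 100 * (C_lt + 0.5 * C_eq) / N}, where
#' \code{C_lt} values are strictly smaller than \code{m} and \code{C_eq}
#' equal it. The rule is symmetric (a value below the whole distribution
#' scores 0, above it 100), handles ties, and is strictly increasing in
#' \code{m} over distributions with distinct values.
#'
#' @param m numeric vector of query values.
#' @param dist a [ValueDistribution-class] or a numeric vector of values.
#' @return numeric vector of percentiles in \code{[0, 100]}.
#' @examples
#' percentileRank(40, c(10, 20, 30, 40))  # (3 + 0.5) / 4 -> 87.5
#' percentileRank(50, 1:100)              # (49 + 0.5) / 100 -> 49.5
#' @export
percentileRank <- function(m, dist) {
  values <- if (is(dist, "ValueDistribution")) dist@values
            else sort(as.numeric(dist))
  n <- length(values)
  if (n == 0L)
    vsError("percentile is undefined over an empty distribution",
            "vs_param_error")
  cLe <- findInterval(m, values)
  cLt <- findInterval(m, values, left.open = TRUE)
  100 * (cLt + 0.5 * (cLe - cLt)) / n
}

#' Summarize the numeric regions annotating one variant
#'
#' Computes the unweighted arithmetic mean \code{m} of the overlapping
#' region values and its mid-rank percentile among all region values of
#' the feature genome-wide.
#'
#' @param values numeric values of the regions overlapping one variant;
#'   must be non-empty (a variant with no overlaps yields no record).
#' @param dist the feature's [ValueDistribution-class].
#' @return named numeric vector with elements \code{mean} and
#'   \code{percentile}.
#' @examples
#' summarizeNumeric(c(2, 4), valueDistributionFromValues(c(1, 2, 3, 4)))
#' @export
summarizeNumeric <- function(values, dist) {
  if (!length(values))
    vsError("cannot summarize an empty region set", "vs_param_error")
  m <- mean(values)
  c(mean = m, percentile = percentileRank(m, dist))
}

#' Build a ValueDistribution directly from values
#'
#' @param values numeric vector.
#' @return a [ValueDistribution-class].
#' @export
valueDistributionFromValues <- function(values) {
  values <- sort(as.numeric(values))
  new("ValueDistribution", n = length(values), values = values)
}

#' Count and extract the unique loci of a variant list
#'
#' Distinct \code{(chromosome, point)} pairs. Input lists retain
#' duplicate loci (e.g. the same clinically reported variant observed in
#' several samples); reports of unique-locus coverage use this
#' deduplication.
#'
#' @param x a [VariantSet-class].
#' @return list with elements \code{count} (number of unique loci) and
#'   \code{variants} (a [VariantSet-class] keeping the first record at
#'   each locus).
#' @aliases dedupUniqueLoci
#' @export
setMethod("dedupUniqueLoci", "VariantSet", function(x) {
  key <- paste(x@chrom, x@point)
  keep <- !duplicated(key)
  dedup <- VariantSet(x@chrom[keep], x@pos[keep], x@ref[keep], x@alt[keep])
  list(count = sum(keep), variants = dedup)
})

#' Generate a 512-bit job identifier
#'
#' Draws 512 bits from the operating system's cryptographic entropy
#' source and renders them as 128 lowercase hexadecimal characters.
#' Errors out if the entropy source is unavailable rather than falling
#' back to a weaker generator; identifiers gate access to job results, so
#' they must be unguessable.
#'
#' @return a 128-character string over \code{[0-9a-f]}.
#' @export
generateJobId <- function() {
  con <- tryCatch(file("/dev/urandom", "rb", raw = TRUE),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con))
    vsError("cryptographic entropy source /dev/urandom unavailable",
            "vs_io_error")
  on.exit(close(con))
  bytes <- readBin(con, "raw", 64L)
  if (length(bytes) != 64L)
    vsError("entropy source returned too few bytes", "vs_io_error")
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

#' Configure an annotation job
#'
#' Validates the flanking window (0 to 1 Mb per side) and the store
#' selection before any work starts; an out-of-range window raises a
#' configuration error.
#'
#' @param window flank size in bp, 0 for exact-location integration.
#' @param storePaths character vector of feature store files (>= 1).
#' @param outputPath where the TSV report will be written.
#' @param jobId optional identifier; a fresh 512-bit one by default.
#' @return a [JobConfig-class].
#' @export
jobConfig <- function(window, storePaths, outputPath = "",
                      jobId = generateJobId()) {
  checkFlank(window)
  if (length(storePaths) < 1L)
    vsError("at least one feature store must be selected",
            "vs_config_error")
  new("JobConfig", window = as.numeric(window), storePaths = storePaths,
      outputPath = outputPath, jobId = jobId)
}

#' Annotate a variant list against feature stores
#'
#' For each selected store, scans the store chromosome by chromosome via
#' the pointer directory, joins it with the variants — [pointJoin()] when
#' \code{window == 0}, [windowJoin()] otherwise — and summarizes the
#' result per variant: the count of overlapping regions plus, for
#' categorical stores, the distinct region labels, or, for numeric
#' stores, the unweighted mean signal and its mid-rank percentile among
#' all the feature's region values. Variants with no overlap in a feature
#' contribute no record for it (they render as blanks in the written
#' table). If the variants and a store share no chromosome, the empty
#' result is legal and a warning is raised.
#'
#' @param variants a non-empty [VariantSet-class].
#' @param stores a [FeatureStore-class], a list of them, or paths.
#' @param window flank in bp per side (0 to 1e6); 0 = exact location.
#' @param jobId job identifier recorded in the table.
#' @return an [AnnotationTable-class].
#' @aliases runAnnotation
#' @export
setMethod("runAnnotation", "VariantSet",
  function(variants, stores, window = 0, jobId = generateJobId()) {
    window <- checkFlank(window)
    if (!length(variants))
      vsError("variant list is empty", "vs_param_error")
    if (is(stores, "FeatureStore")) stores <- list(stores)
    stores <- lapply(stores, function(s) {
      if (is.character(s)) openFeatureStore(s) else s
    })
    if (!length(stores))
      vsError("at least one feature store must be selected",
              "vs_config_error")

    vdf <- as.data.frame(variants)
    inputOrd <- order(vdf$inputIndex)
    variantRowOf <- integer(length(variants))
    variantRowOf[inputOrd] <- seq_along(inputOrd)  # sorted idx -> table row

    featNames <- vapply(stores, featureName, "")
    records <- list()
    vChroms <- unique(variants@chrom)
    for (s in stores) {
      shared <- intersect(vChroms, s@directory$chrom)
      if (!length(shared))
        warning(sprintf(
          "feature '%s' and the variant list share no chromosome",
          s@featureName))
      regions <- do.call(rbind, lapply(s@directory$chrom, scanRegions,
                                       store = s))
      if (is.null(regions))
        regions <- data.frame(chrom = character(), start = integer(),
                              end = integer(), value = character())
      vm <- if (window == 0) pointJoin(variants, regions)
            else windowJoin(variants, regions, window)
      p <- joinPairs(vm)
      if (!nrow(p)) next
      bySorted <- split(seq_len(nrow(p)), p$variant)
      numericStore <- s@valueType == "numeric"
      dist <- if (numericStore) valueDistribution(s) else NULL
      recs <- lapply(names(bySorted), function(vi) {
        rows <- bySorted[[vi]]
        if (numericStore) {
          sm <- summarizeNumeric(p$value[rows], dist)
          data.frame(variantRow = variantRowOf[as.integer(vi)],
                     feature = s@featureName, count = length(rows),
                     labels = NA_character_, mean = unname(sm["mean"]),
                     percentile = unname(sm["percentile"]))
        } else {
          data.frame(variantRow = variantRowOf[as.integer(vi)],
                     feature = s@featureName, count = length(rows),
                     labels = paste(unique(p$value[rows]), collapse = ","),
                     mean = NA_real_, percentile = NA_real_)
        }
      })
      records[[length(records) + 1L]] <- do.call(rbind, recs)
    }
    records <- if (length(records)) do.call(rbind, records)
      else data.frame(variantRow = integer(), feature = character(),
                      count = integer(), labels = character(),
                      mean = numeric(), percentile = numeric())
    records <- records[order(match(records$feature, featNames),
                             records$variantRow), , drop = FALSE]
    rownames(records) <- NULL
    new("AnnotationTable",
        variants = vdf[inputOrd, c("chrom", "pos", "ref", "alt", "kind",
                                   "point")],
        features = featNames, records = records,
        window = as.numeric(window), jobId = jobId)
  })

#' Write an annotation table
#'
#' Writes one row per input variant, in input order, with the variant
#' columns followed by one column group per feature in selection order:
#' overlapping-region count, value (distinct labels for categorical
#' features, mean signal for numeric ones) and percentile (numeric
#' only). Cells of (variant, feature) pairs without overlap are blank, so
#' every processed variant is visible in the output even when nothing
#' annotates it. The TSV dialect is UTF-8, tab-separated, "\n" line ends,
#' header mandatory. Identical inputs and configuration produce
#' byte-identical files.
#'
#' @param x an [AnnotationTable-class].
#' @param path output file.
#' @param format only \code{"tsv"} is implemented; \code{"spreadsheet"}
#'   raises an error pointing at TSV (any spreadsheet program imports
#'   it).
#' @return \code{path}, invisibly.
#' @aliases writeTable
#' @export
setMethod("writeTable", "AnnotationTable",
  function(x, path, format = c("tsv", "spreadsheet")) {
    format <- match.arg(format)
    if (format == "spreadsheet")
      vsError("spreadsheet output is not available; write TSV and import it",
              "vs_config_error")
    v <- x@variants
    num <- function(z) ifelse(is.na(z), "", sprintf("%.15g", z))
    cells <- data.frame(chrom = v$chrom, pos = as.character(v$pos),
                        ref = v$ref, alt = v$alt, kind = v$kind,
                        stringsAsFactors = FALSE)
    for (f in x@features) {
      r <- x@records[x@records$feature == f, , drop = FALSE]
      count <- rep("", nrow(v)); val <- rep("", nrow(v))
      pct <- rep("", nrow(v))
      if (nrow(r)) {
        count[r$variantRow] <- as.character(r$count)
        val[r$variantRow] <- ifelse(is.na(r$mean), r$labels, num(r$mean))
        pct[r$variantRow] <- num(r$percentile)
      }
      cells[[paste0(f, ".count")]] <- count
      cells[[paste0(f, ".value")]] <- val
      cells[[paste0(f, ".percentile")]] <- pct
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(names(cells), collapse = "\t"),
                 do.call(paste, c(unname(cells), sep = "\t"))),
               con, sep = "\n", useBytes = TRUE)
    invisible(path)
  })
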