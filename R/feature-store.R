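## Import of BED-style feature tracks and the sorted, pointer-indexed
## on-disk store.
##
## Store layout (little-endian):
##   magic "VASF" | version u8 = 1
##   metadata: u8 name length, name bytes; u8 value type (0 numeric,
##     1 categorical); string table: u32 entry count, entries u16 length +
##     bytes (categorical stores only)
##   directory: u32 chromosome count; entries: u8 name length, name bytes,
##     u64 absolute byte offset of the first record, u64 record count
##   records, per chromosome: start u32, end u32, value f32 (numeric) or
##     0-based label index u32 (categorical) — 12 bytes per record
##   footer (numeric stores): u64 count, count x f32 sorted values

RECORD_BYTES <- 12L

#' Import feature regions from BED-style text
#'
#' Reads 3-5 column BED or 4-column bedGraph-style text into a region
#' data.frame. Coordinates are taken as 0-based half-open, as in BED.
#' When \code{valueColumn} is given, the numeric value is read from that
#' column; otherwise a 4th column (the BED name) is used as a categorical
#' label, and 3-column records get the constant label \code{"present"}.
#'
#' @param input file path, connection, or character vector of lines.
#' @param valueColumn optional 1-based column index of the numeric value
#'   (e.g. 4 for bedGraph, 5 for BED score).
#' @return data.frame with columns chrom, start, end, value.
#' @examples
#' importBed("chr1\t10\t20\tpeak1\t7.5", valueColumn = 5)
#' @export
importBed <- function(input, valueColumn = NULL) {
  lines <- if (inherits(input, "connection") ||
               (is.character(input) && length(input) == 1 &&
                file.exists(input))) readLines(input) else as.character(input)
  lineNo <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = character()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    vsError(sprintf("fewer than 3 BED columns at line %d",
                    lineNo[which(nf < 3)[1]]), "vs_format_error")
  chrom <- normalizeChrom(vapply(fields, `[`, "", 1L))
  startStr <- vapply(fields, `[`, "", 2L)
  endStr <- vapply(fields, `[`, "", 3L)
  badCoord <- which(!grepl("^[0-9]+$", startStr) | !grepl("^[0-9]+$", endStr))
  if (length(badCoord))
    vsError(sprintf("malformed coordinates at line %d", lineNo[badCoord[1]]),
            "vs_record_error")
  start <- as.integer(startStr); end <- as.integer(endStr)
  badIv <- which(start >= end)
  if (length(badIv))
    vsError(sprintf("empty or inverted interval [%d, %d) at line %d",
                    start[badIv[1]], end[badIv[1]], lineNo[badIv[1]]),
            "vs_record_error")
  if (!is.null(valueColumn)) {
    short <- which(nf < valueColumn)
    if (length(short))
      vsError(sprintf("missing value column %d at line %d", valueColumn,
                      lineNo[short[1]]), "vs_record_error")
    valStr <- vapply(fields, `[`, "", as.integer(valueColumn))
    value <- suppressWarnings(as.numeric(valStr))
    badVal <- which(is.na(value))
    if (length(badVal))
      vsError(sprintf("non-numeric value '%s' at line %d", valStr[badVal[1]],
                      lineNo[badVal[1]]), "vs_record_error")
  } else {
    value <- ifelse(nf >= 4, vapply(fields, `[`, "", 4L), "present")
  }
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

writeU <- function(con, x, nbytes) writeBin(intToRawLE(x, nbytes), con)

#' Build a sorted on-disk feature store
#'
#' Sorts the regions by (chromosome, start, end), writes them to a binary
#' store file together with a chromosome pointer directory for direct
#' access, and — for numeric stores — a footer with the sorted array of
#' all region values used for percentile reporting. Regions may arrive
#' unsorted and may overlap or nest; they are preserved as-is, never
#' merged. Numeric values are stored as 32-bit floats.
#'
#' @param regions data.frame with columns chrom, start, end and optionally
#'   value (as from [importBed()]).
#' @param name feature name recorded in the store.
#' @param valueType "numeric" or "categorical".
#' @param path file to write.
#' @return a [FeatureStore-class] opened on the written file.
#' @examples
#' f <- tempfile(fileext = ".vasf")
#' st <- buildFeatureStore(
#'   data.frame(chrom = "chr1", start = c(50L, 10L), end = c(60L, 20L),
#'              value = c(1, 2)),
#'   name = "toy", valueType = "numeric", path = f)
#' scanRegions(st, "chr1")
#' @export
buildFeatureStore <- function(regions, name,
                              valueType = c("numeric", "categorical"),
                              path) {
  valueType <- match.arg(valueType)
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    vsError("regions must have chrom, start, end columns", "vs_param_error")
  n <- nrow(regions)
  chrom <- normalizeChrom(as.character(regions$chrom))
  start <- as.numeric(regions$start); end <- as.numeric(regions$end)
  if (n && any(start >= end))
    vsError(sprintf("empty or inverted interval at region %d",
                    which(start >= end)[1]), "vs_record_error")
  if (n && any(start < 0))
    vsError("region starts must be >= 0", "vs_record_error")
  value <- if ("value" %in% names(regions)) regions$value
           else rep("present", n)
  if (valueType == "numeric") {
    if (!is.numeric(value)) {
      conv <- suppressWarnings(as.numeric(value))
      if (n && anyNA(conv))
        vsError("non-numeric value in declared-numeric store",
                "vs_type_error")
      value <- conv
    }
    stringTable <- character(0)
    valCode <- value
  } else {
    value <- as.character(value)
    stringTable <- sort(unique(value))
    valCode <- match(value, stringTable) - 1L  # 0-based index
  }

  ord <- order(chrom, start, end, method = "radix")
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  valCode <- if (n) valCode[ord] else valCode

  chroms <- unique(chrom)
  counts <- as.numeric(table(factor(chrom, levels = chroms)))

  nameBytes <- charToRaw(name)
  if (length(nameBytes) > 255)
    vsError("feature name longer than 255 bytes", "vs_encoding_error")
  tableBytes <- lapply(stringTable, charToRaw)
  metaLen <- 1 + length(nameBytes) + 1 + 4 +
    sum(vapply(tableBytes, length, 0L) + 2)
  dirLen <- 4 + sum(1 + nchar(chroms, type = "bytes") + 8 + 8)
  recordBase <- 5 + metaLen + dirLen
  offsets <- recordBase + cumsum(c(0, head(counts, -1))) * RECORD_BYTES

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VASF"), con); writeBin(as.raw(1L), con)
  writeBin(as.raw(length(nameBytes)), con); writeBin(nameBytes, con)
  writeBin(as.raw(if (valueType == "numeric") 0L else 1L), con)
  writeU(con, length(tableBytes), 4)
  for (tb in tableBytes) {
    writeU(con, length(tb), 2); writeBin(tb, con)
  }
  writeU(con, length(chroms), 4)
  for (i in seq_along(chroms)) {
    cb <- charToRaw(chroms[i])
    writeBin(as.raw(length(cb)), con); writeBin(cb, con)
    writeU(con, offsets[i], 8); writeU(con, counts[i], 8)
  }
  # interleaved 12-byte records, written chromosome by chromosome
  if (n) {
    rec <- matrix(as.raw(0), nrow = RECORD_BYTES, ncol = n)
    rec[1:4, ] <- matrix(intToRawLE(start, 4), nrow = 4)
    rec[5:8, ] <- matrix(intToRawLE(end, 4), nrow = 4)
    rec[9:12, ] <- if (valueType == "numeric")
      matrix(writeBin(as.numeric(valCode), raw(), size = 4,
                      endian = "little"), nrow = 4)
    else matrix(intToRawLE(valCode, 4), nrow = 4)
    writeBin(as.vector(rec), con)
  }
  if (valueType == "numeric") {
    sortedVals <- sort(readBin(writeBin(as.numeric(valCode), raw(), size = 4,
                                        endian = "little"),
                               "numeric", n = n, size = 4,
                               endian = "little"))
    writeU(con, n, 8)
    writeBin(sortedVals, con, size = 4, endian = "little")
  }
  close(con); on.exit()
  openFeatureStore(path)
}

#' Open an existing feature store
#'
#' Reads the header, metadata, pointer directory and (for numeric stores)
#' the sorted value footer; region records themselves are only read on
#' demand by [scanRegions()].
#'
#' @param path path to a store file written by [buildFeatureStore()].
#' @return a [FeatureStore-class].
#' @export
openFeatureStore <- function(path) {
  if (!file.exists(path))
    vsError(sprintf("feature store '%s' does not exist", path),
            "vs_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "VASF"))
    vsError(sprintf("bad magic in '%s': not a feature store", path),
            "vs_format_error")
  version <- as.integer(readBin(con, "raw", 1))
  if (version != 1L)
    vsError(sprintf("unsupported store version %d", version),
            "vs_format_error")
  nameLen <- as.integer(readBin(con, "raw", 1))
  featureName <- rawToChar(readBin(con, "raw", nameLen))
  typeCode <- as.integer(readBin(con, "raw", 1))
  valueType <- if (typeCode == 0L) "numeric" else "categorical"
  nTable <- rawToIntLE(readBin(con, "raw", 4), 4)
  stringTable <- character(nTable)
  for (i in seq_len(nTable)) {
    len <- rawToIntLE(readBin(con, "raw", 2), 2)
    stringTable[i] <- rawToChar(readBin(con, "raw", len))
  }
  nChrom <- rawToIntLE(readBin(con, "raw", 4), 4)
  dchrom <- character(nChrom); doffset <- numeric(nChrom)
  dcount <- numeric(nChrom)
  for (i in seq_len(nChrom)) {
    len <- as.integer(readBin(con, "raw", 1))
    dchrom[i] <- rawToChar(readBin(con, "raw", len))
    doffset[i] <- rawToIntLE(readBin(con, "raw", 8), 8)
    dcount[i] <- rawToIntLE(readBin(con, "raw", 8), 8)
  }
  nTotal <- sum(dcount)
  sortedValues <- numeric(0)
  if (valueType == "numeric") {
    footerAt <- if (nChrom) doffset[nChrom] + dcount[nChrom] * RECORD_BYTES
                else seek(con)
    seek(con, footerAt)
    nVals <- rawToIntLE(readBin(con, "raw", 8), 8)
    sortedValues <- readBin(con, "numeric", n = nVals, size = 4,
                            endian = "little")
  }
  new("FeatureStore", path = path, featureName = featureName,
      valueType = valueType,
      directory = data.frame(chrom = dchrom, offset = doffset,
                             count = dcount),
      nRegions = nTotal, stringTable = stringTable,
      sortedValues = sortedValues)
}

#' Scan one chromosome of a feature store
#'
#' Seeks directly to the chromosome's byte offset recorded in the pointer
#' directory and reads exactly that chromosome's records, in sorted
#' (start, end) order, without touching records of preceding chromosomes.
#' A chromosome absent from the directory yields an empty stream, not an
#' error. The returned data.frame carries attributes \code{offsetUsed}
#' and \code{recordsRead} so callers can verify the access pattern.
#'
#' @param store a [FeatureStore-class].
#' @param chrom one chromosome name ("chr" prefix optional).
#' @return data.frame with columns chrom, start, end, value.
#' @aliases scanRegions
#' @export
setMethod("scanRegions", c("FeatureStore", "character"),
  function(store, chrom) {
    chrom <- normalizeChrom(chrom)
    d <- store@directory
    i <- match(chrom, d$chrom)
    if (is.na(i)) {
      out <- data.frame(chrom = character(), start = integer(),
                        end = integer(),
                        value = if (store@valueType == "numeric") numeric()
                                else character())
      attr(out, "offsetUsed") <- NA_real_
      attr(out, "recordsRead") <- 0
      return(out)
    }
    con <- file(store@path, "rb")
    on.exit(close(con))
    seek(con, d$offset[i])
    count <- d$count[i]
    r <- readBin(con, "raw", count * RECORD_BYTES)
    m <- matrix(r, nrow = RECORD_BYTES)
    start <- as.integer(rawToIntLE(as.vector(m[1:4, , drop = FALSE]), 4))
    end <- as.integer(rawToIntLE(as.vector(m[5:8, , drop = FALSE]), 4))
    value <- if (store@valueType == "numeric") {
      readBin(as.vector(m[9:12, , drop = FALSE]), "numeric", n = count,
              size = 4, endian = "little")
    } else {
      store@stringTable[rawToIntLE(as.vector(m[9:12, , drop = FALSE]), 4) + 1]
    }
    out <- data.frame(chrom = rep(chrom, count), start = start, end = end,
                      value = value, stringsAsFactors = FALSE)
    attr(out, "offsetUsed") <- d$offset[i]
    attr(out, "recordsRead") <- count
    out
  })

#' Genome-wide value distribution of a numeric store
#'
#' Returns the exact sorted multiset of all region values, against which
#' window means are ranked by [percentileRank()]. Only defined for
#' numeric stores.
#'
#' @param store a [FeatureStore-class] with numeric values.
#' @return a [ValueDistribution-class].
#' @aliases valueDistribution
#' @export
setMethod("valueDistribution", "FeatureStore", function(store) {
  if (store@valueType != "numeric")
    vsError("value distribution is undefined for categorical stores",
            "vs_type_error")
  new("ValueDistribution", n = store@nRegions, values = store@sortedValues)
})
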