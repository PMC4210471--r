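## Parsing of variant lists (VCF / whitespace-delimited), classification,
## and the compact delta-varint transfer codec.

#' Representative 0-based point of a variant
#'
#' The coordinate at which a variant takes part in exact-location
#' integration: the exact location (\code{pos - 1}) for an SNV, an
#' insertion or a point-only record, and the mid-point of the deleted span
#' for a deletion. For a deletion whose REF spans the 0-based half-open
#' interval \code{[s, s + |ref|)} the mid-point is
#' \code{floor((s + s + |ref| - 1) / 2)}, i.e. the floor of the average of
#' the first and last deleted bases — deterministic for spans of even
#' length.
#'
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles ("" when absent).
#' @param kind optional character vector of kinds; derived from the allele
#'   lengths when omitted.
#' @return integer vector of 0-based coordinates.
#' @examples
#' representativePoint(500, "A", "T")            # SNV -> 499
#' representativePoint(1000, "A", "ACGT")        # insertion -> 999
#' representativePoint(100, strrep("A", 11), "A")# deletion span [99,110) -> 104
#' @export
representativePoint <- function(pos, ref = "", alt = "", kind = NULL) {
  n <- max(length(pos), length(ref), length(alt))
  pos <- rep_len(as.numeric(pos), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (is.null(kind)) kind <- classifyVariant(ref, alt)
  kind <- rep_len(kind, n)
  s <- pos - 1
  pt <- s
  del <- kind == "deletion"
  if (any(del)) pt[del] <- s[del] + (nchar(ref[del]) - 1) %/% 2
  as.integer(pt)
}

classifyVariant <- function(ref, alt) {
  kind <- rep("point", length(ref))
  hasAllele <- !(ref == "" & alt == "")
  nr <- nchar(ref)[hasAllele]
  na <- nchar(alt)[hasAllele]
  kind[hasAllele] <- ifelse(na > nr, "insertion",
                     ifelse(nr > na, "deletion", "SNV"))
  kind
}

#' Construct a VariantSet
#'
#' Classifies each record (SNV when the allele lengths are equal,
#' insertion when ALT is longer, deletion when REF is longer, point-only
#' when no alleles are given), computes representative points and stores
#' the records sorted per chromosome by point. The sort is stable, so
#' records sharing a point keep their input order, and the original order
#' is preserved in \code{inputIndex}.
#'
#' @param chrom character chromosome names (a missing "chr" prefix is
#'   added).
#' @param pos integer 1-based positions.
#' @param ref,alt character alleles, "" when absent.
#' @return a [VariantSet-class] object.
#' @examples
#' VariantSet(c("chr1", "1"), c(100L, 50L), c("A", ""), c("T", ""))
#' @export
VariantSet <- function(chrom, pos, ref = "", alt = "") {
  pos <- as.numeric(pos)
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep_len(chrom, n)
  if (length(chrom) != n)
    vsError("chrom and pos must have equal length", "vs_param_error")
  if (n && (anyNA(pos) || any(pos < 1) || any(pos != floor(pos))))
    vsError("positions must be integers >= 1", "vs_param_error")
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  chrom <- normalizeChrom(as.character(chrom))
  kind <- classifyVariant(ref, alt)
  point <- representativePoint(pos, ref, alt, kind)
  ord <- order(chrom, point, method = "radix")
  new("VariantSet", chrom = chrom[ord], pos = as.integer(pos)[ord],
      ref = ref[ord], alt = alt[ord], kind = kind[ord], point = point[ord],
      inputIndex = as.integer(seq_len(n))[ord])
}

#' Parse a variant list from VCF or whitespace-delimited text
#'
#' Reads a variant list and returns a sorted [VariantSet-class]. Two
#' formats are supported: VCF (columns CHROM POS ID REF ALT ...; header
#' and comment lines starting with '#' are skipped) and whitespace-
#' delimited lists (columns chrom, position, optional ref, optional alt).
#' In \code{"auto"} mode the format is detected from a
#' \code{##fileformat=VCF} header line or, failing that, from the column
#' count of the first data line (5 or more columns reads as VCF).
#'
#' Only the first ALT allele of a multi-allelic VCF record is parsed; the
#' remaining alternates are ignored. Records with a missing allele
#' (\code{"."}) are treated as point-only.
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @param format one of "auto", "vcf", "list".
#' @return a [VariantSet-class].
#' @examples
#' parseVariants(c("chr1 12345", "chr2 678"))
#' @export
parseVariants <- function(input, format = c("auto", "vcf", "list")) {
  format <- match.arg(format)
  lines <- if (inherits(input, "connection") ||
               (is.character(input) && length(input) == 1 &&
                file.exists(input))) readLines(input) else as.character(input)
  lineNo <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]

  isComment <- startsWith(lines, "#")
  if (format == "auto") {
    if (any(startsWith(lines, "##fileformat=VCF"))) {
      format <- "vcf"
    } else {
      first <- lines[!isComment][1]
      if (is.na(first))
        vsError("no data lines found", "vs_format_error")
      ncol <- length(strsplit(trimws(first), "[ \t]+")[[1]])
      format <- if (ncol >= 5) "vcf" else "list"
    }
  }

  body <- lines[!isComment]
  bodyNo <- lineNo[!isComment]
  if (!length(body))
    return(VariantSet(character(), integer()))
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)

  if (format == "vcf") {
    bad <- which(nf < 5)
    if (length(bad))
      vsError(sprintf(
        "not a VCF record (fewer than 5 columns) at line %d", bodyNo[bad[1]]),
        "vs_format_error")
    chrom <- vapply(fields, `[`, "", 1L)
    posStr <- vapply(fields, `[`, "", 2L)
    ref <- toupper(vapply(fields, `[`, "", 4L))
    alt <- toupper(sub(",.*", "", vapply(fields, `[`, "", 5L)))
    miss <- ref == "." | alt == "."
    ref[miss] <- ""; alt[miss] <- ""
  } else {
    bad <- which(nf < 2 | nf > 4)
    if (length(bad))
      vsError(sprintf(
        "expected 2-4 whitespace-delimited columns at line %d", bodyNo[bad[1]]),
        "vs_format_error")
    chrom <- vapply(fields, `[`, "", 1L)
    posStr <- vapply(fields, `[`, "", 2L)
    ref <- toupper(vapply(fields, function(f) if (length(f) >= 3) f[3] else "",
                          ""))
    alt <- toupper(vapply(fields, function(f) if (length(f) >= 4) f[4] else "",
                          ""))
  }

  badPos <- which(!grepl("^[0-9]+$", posStr) | posStr == "0")
  if (length(badPos))
    vsError(sprintf("malformed coordinate '%s' at line %d",
                    posStr[badPos[1]], bodyNo[badPos[1]]),
            "vs_parse_error")
  VariantSet(chrom, as.numeric(posStr), ref, alt)
}

## ---- little-endian binary helpers ----------------------------------------

intToRawLE <- function(x, nbytes) {
  x <- as.numeric(x)
  out <- matrix(as.raw(0), nrow = nbytes, ncol = length(x))
  for (k in seq_len(nbytes)) {
    out[k, ] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  as.vector(out)
}

rawToIntLE <- function(r, nbytes) {
  m <- matrix(as.integer(r), nrow = nbytes)
  as.numeric(256^(seq_len(nbytes) - 1) %*% m)
}

#' Compress a variant list to the compact transfer payload
#'
#' Encodes only the (chromosome, point) locations of a [VariantSet-class]
#' as per-chromosome arrays: within each chromosome the first 0-based
#' point is stored absolute and every subsequent point as its delta from
#' the previous one, both as unsigned LEB128 varints. Repetitive text
#' (chromosome names, alleles, any other columns) is dropped, so three
#' million human-scale variants encode to a few megabytes. The layout is
#' deterministic: the same variant set always yields byte-identical
#' payloads. The payload never exceeds
#' \code{16 + sum(2 + nchar(name) + 8 + 5 * count)} bytes, which is
#' asserted on every call.
#'
#' @param x a [VariantSet-class] (for \code{compressVariants}) or a
#'   [CompressedVariants-class] / raw payload (for
#'   \code{decompressVariants}).
#' @return \code{compressVariants}: a [CompressedVariants-class];
#'   \code{decompressVariants}: a [VariantSet-class] of point-only
#'   variants — the exact (chromosome, point) multiset that was encoded.
#' @examples
#' vs <- VariantSet("chr1", c(1000L, 1500L))
#' cv <- compressVariants(vs)
#' decompressVariants(cv)
#' @aliases compressVariants decompressVariants
#' @export
setMethod("compressVariants", "VariantSet", function(x) {
  chroms <- unique(x@chrom)  # already lexicographically sorted
  ptsByChrom <- split(x@point, factor(x@chrom, levels = chroms))
  header <- c(charToRaw("VASC"), as.raw(1L), intToRawLE(length(chroms), 4))
  blocks <- vector("list", length(chroms))
  counts <- integer(length(chroms))
  offsets <- numeric(length(chroms))
  at <- length(header)
  for (i in seq_along(chroms)) {
    name <- chroms[i]
    nameBytes <- charToRaw(name)
    if (length(nameBytes) > 255)
      vsError(sprintf("chromosome name '%s' longer than 255 bytes", name),
              "vs_encoding_error")
    pts <- ptsByChrom[[i]]
    enc <- .encode_positions_cpp(pts)
    blocks[[i]] <- c(as.raw(length(nameBytes)), nameBytes,
                     intToRawLE(length(pts), 8), enc)
    counts[i] <- length(pts)
    offsets[i] <- at
    at <- at + length(blocks[[i]])
  }
  payload <- c(header, unlist(blocks))
  bound <- 16 + sum(2 + nchar(chroms) + 8 + 5 * counts)
  stopifnot(length(payload) <= bound)
  new("CompressedVariants", payload = payload,
      directory = data.frame(chrom = chroms, count = counts,
                             offset = offsets))
})

#' @rdname compressVariants
#' @export
setMethod("decompressVariants", "CompressedVariants", function(x) {
  decompressVariants(x@payload)
})

#' @rdname compressVariants
#' @export
setMethod("decompressVariants", "raw", function(x) {
  if (length(x) < 9 || !identical(rawToChar(x[1:4]), "VASC"))
    vsError("bad magic: not a compressed variant payload", "vs_format_error")
  if (as.integer(x[5]) != 1L)
    vsError(sprintf("unsupported payload version %d", as.integer(x[5])),
            "vs_format_error")
  nChrom <- rawToIntLE(x[6:9], 4)
  at <- 9  # bytes consumed so far (0-based offset of next byte + 1 == at + 1)
  need <- function(k) {
    if (at + k > length(x))
      vsError(sprintf("corrupt payload: truncated at byte offset %d",
                      length(x)), "vs_corruption_error")
  }
  chrom <- character(0); point <- integer(0)
  for (i in seq_len(nChrom)) {
    need(1); nameLen <- as.integer(x[at + 1]); at <- at + 1
    need(nameLen); name <- rawToChar(x[(at + 1):(at + nameLen)])
    at <- at + nameLen
    need(8); count <- rawToIntLE(x[(at + 1):(at + 8)], 8); at <- at + 8
    dec <- tryCatch(.decode_positions_cpp(x, at, count),
                    error = function(e)
                      vsError(conditionMessage(e), "vs_corruption_error"))
    at <- at + dec$bytes_consumed
    chrom <- c(chrom, rep(name, count))
    point <- c(point, dec$positions)
  }
  VariantSet(chrom, point + 1)
})
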