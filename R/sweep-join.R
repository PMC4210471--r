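## The two linear-time sweep-line (sort-merge) joins and the quadratic
## brute-force oracle used to verify them.

checkFlank <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1e6)
    vsError("flanking window must be a single value between 0 and 1000000 bp",
            c("vs_config_error", "vs_param_error"))
  as.integer(w)
}

regionChromSplit <- function(regions) {
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    vsError("regions must have chrom, start, end columns", "vs_param_error")
  regions$chrom <- normalizeChrom(as.character(regions$chrom))
  split(seq_len(nrow(regions)), regions$chrom)
}

sweepJoinImpl <- function(variants, regions, w, windowed) {
  stopifnot(is(variants, "VariantSet"))
  hasValue <- "value" %in% names(regions)
  ridxByChrom <- regionChromSplit(regions)
  vidxByChrom <- split(seq_along(variants@chrom), variants@chrom)
  chroms <- sort(union(names(vidxByChrom), names(ridxByChrom)))
  ins <- 0; rem <- 0
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    vi <- vidxByChrom[[ch]]; if (is.null(vi)) vi <- integer(0)
    ri <- ridxByChrom[[ch]]; if (is.null(ri)) ri <- integer(0)
    pts <- variants@point[vi]
    res <- if (windowed)
      .window_join_cpp(pts, regions$start[ri], regions$end[ri], w)
    else
      .point_join_cpp(pts, regions$start[ri], regions$end[ri])
    ins <- ins + res$insertions
    rem <- rem + res$removals
    if (length(res$variant)) {
      gi <- ri[res$region]
      out[[k]] <- data.frame(
        variant = vi[res$variant], region = gi, chrom = ch,
        start = regions$start[gi], end = regions$end[gi],
        value = if (hasValue) regions$value[gi] else NA,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(pairs))
    pairs <- data.frame(variant = integer(), region = integer(),
                        chrom = character(), start = integer(),
                        end = integer(), value = logical(0))
  new("VariantMap", pairs = pairs,
      stats = list(insertions = ins, removals = rem,
                   nVariants = length(variants),
                   nRegions = nrow(regions)))
}

#' Sweep-line joins between variants and feature regions
#'
#' Both joins process each chromosome in a single coordinated scan over
#' the sorted variant points and sorted region starts, maintaining
#' identity-keyed active sets ("queues"): open feature regions and, for
#' the windowed join, open variant windows.
#'
#' \code{pointJoin} annotates a variant with every region whose half-open
#' interval contains its representative point: \code{start <= p < end}.
#' Scan actions are: at a region start, add the region to the feature
#' queue; at a region end, remove it; at a variant point, annotate the
#' variant with every region currently in the queue.
#'
#' \code{windowJoin} annotates a variant with every region overlapping its
#' flanking window \code{[max(0, p - w), p + w + 1)}. Scan actions are: at
#' a window start, add the variant to the variant queue and annotate it
#' with every open region; at a window end, remove it; at a region start,
#' add the region to the feature queue and annotate every variant in the
#' variant queue with it; at a region end, remove it. Each (variant,
#' region) pair is discovered exactly once because whichever of the two
#' intervals opens second triggers the annotation. With \code{w = 0} the
#' windowed join reduces exactly to the point join.
#'
#' Coordinate ties resolve in the order region end < window end < region
#' start < variant point / window start, which encodes the half-open
#' convention: a region ending at \code{c} never annotates a point or
#' window starting at \code{c}, while a region starting at \code{c}
#' always annotates a variant point at \code{c}.
#'
#' \code{bruteForceJoin} is the quadratic all-pairs reference: it tests
#' every same-chromosome (variant, region) pair directly and is used as
#' the correctness oracle for the sweeps.
#'
#' @param variants a [VariantSet-class] (sorted by construction).
#' @param regions data.frame with columns chrom, start, end and optionally
#'   value, sorted by start within each chromosome (as returned by
#'   [scanRegions()] or [buildFeatureStore()]); unsorted input raises a
#'   precondition error.
#' @param w flank size in bp per side, 0 to 1e6 (1 Mb).
#' @return a [VariantMap-class]; its \code{variant} column indexes the
#'   sorted variant set.
#' @examples
#' vs <- VariantSet("chr1", c(6L, 11L))  # points 5 and 10
#' rg <- data.frame(chrom = "chr1", start = 5L, end = 10L, value = 1)
#' joinPairs(pointJoin(vs, rg))   # point 5 in [5,10); point 10 not
#' @name sweepJoins
#' @aliases pointJoin windowJoin bruteForceJoin
NULL

#' @rdname sweepJoins
#' @export
setMethod("pointJoin", c("VariantSet", "data.frame"),
  function(variants, regions) {
    sweepJoinImpl(variants, regions, 0L, windowed = FALSE)
  })

#' @rdname sweepJoins
#' @export
setMethod("windowJoin", c("VariantSet", "data.frame"),
  function(variants, regions, w) {
    w <- checkFlank(w)
    sweepJoinImpl(variants, regions, w, windowed = TRUE)
  })

#' @rdname sweepJoins
#' @export
setMethod("bruteForceJoin", c("VariantSet", "data.frame"),
  function(variants, regions, w = 0) {
    w <- checkFlank(w)
    hasValue <- "value" %in% names(regions)
    ridxByChrom <- regionChromSplit(regions)
    vidxByChrom <- split(seq_along(variants@chrom), variants@chrom)
    out <- list()
    for (ch in intersect(names(vidxByChrom), names(ridxByChrom))) {
      vi <- vidxByChrom[[ch]]; ri <- ridxByChrom[[ch]]
      ws <- pmax(0, variants@point[vi] - w)
      we <- variants@point[vi] + w + 1
      # window [ws, we) overlaps region [s, e) iff ws < e and s < we
      hit <- outer(ws, regions$end[ri], `<`) &
             outer(we, regions$start[ri], `>`)
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) {
        gi <- ri[idx[, 2]]
        out[[ch]] <- data.frame(
          variant = vi[idx[, 1]], region = gi, chrom = ch,
          start = regions$start[gi], end = regions$end[gi],
          value = if (hasValue) regions$value[gi] else NA,
          stringsAsFactors = FALSE)
      }
    }
    pairs <- do.call(rbind, unname(out))
    if (is.null(pairs))
      pairs <- data.frame(variant = integer(), region = integer(),
                          chrom = character(), start = integer(),
                          end = integer(), value = logical(0))
    pairs <- pairs[order(pairs$variant, pairs$region), , drop = FALSE]
    rownames(pairs) <- NULL
    new("VariantMap", pairs = pairs,
        stats = list(insertions = NA_real_, removals = NA_real_,
                     nVariants = length(variants),
                     nRegions = nrow(regions)))
  })
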