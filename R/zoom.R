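# Zoom-dependent granularity. The zoom measure is bases per pixel (bp/px):
#   <= 1/8 bp/px   -> "sequence" tier (>= 8 px per base: room for letters)
#   <= threshold   -> "individual" tier (one glyph per feature)
#   >  threshold   -> "summary" tier (fixed-width bins; width snapped to the
#                     smallest power of 10 >= bp/px so nearby zoom levels
#                     share cached bin payloads)
# The individual/summary boundary defaults to 1000 bp/px and is configurable.

SEQUENCE_TIER_MAX_BPP <- 1 / 8

#' Construct a zoom tier
#'
#' Normally obtained from [choose_tier()]; the constructor is exported so
#' payload reducers can be driven directly.
#'
#' @param bases_per_pixel Positive zoom measure.
#' @param kind `"sequence"`, `"individual"` or `"summary"`.
#' @param bin_width Bin width in bp (summary kind only).
#' @return An object of class `zoom_tier`.
#' @export
zoom_tier <- function(bases_per_pixel, kind, bin_width = NA_real_) {
  kind <- match.arg(kind, c("sequence", "individual", "summary"))
  if (bases_per_pixel <= 0) stop_argument("bases_per_pixel must be positive")
  if (kind == "summary" && (is.na(bin_width) || bin_width < 1))
    stop_argument("summary tier requires a bin_width >= 1")
  structure(list(bases_per_pixel = bases_per_pixel, kind = kind,
                 bin_width = as.numeric(bin_width)),
            class = "zoom_tier")
}

#' @export
print.zoom_tier <- function(x, ...) {
  cat(sprintf("<zoom_tier> %s (%.4g bp/px%s)\n", x$kind, x$bases_per_pixel,
              if (x$kind == "summary")
                sprintf(", bin %s bp", format(x$bin_width, scientific = FALSE))
              else ""))
  invisible(x)
}

#' Label used as the cache-tier component of a cache key
#' @param tier A [zoom_tier()].
#' @return `"sequence"`, `"individual"`, or `"bin:<width>"`.
#' @export
tier_label <- function(tier) {
  if (tier$kind == "summary")
    sprintf("bin:%s", format(tier$bin_width, scientific = FALSE))
  else tier$kind
}

#' Choose the rendering granularity for a viewport
#'
#' Data is requested and drawn at a granularity decided by zoom level:
#' bases-per-pixel is the viewport span divided by its pixel width. Boundaries
#' are inclusive on the finer side: exactly 1/8 bp/px is still sequence tier,
#' exactly `individual_threshold` bp/px is still individual tier.
#'
#' @param viewport A [viewport()].
#' @param individual_threshold Individual/summary boundary in bp/px
#'   (default 1000).
#' @return A [zoom_tier()].
#' @examples
#' choose_tier(viewport("chr1", 1, 100, 1000))   # sequence
#' choose_tier(viewport("chr1", 1, 1e6, 1000))   # individual (boundary)
#' choose_tier(viewport("chr1", 1, 1e8, 1000))   # summary, 1e5 bp bins
#' @export
choose_tier <- function(viewport, individual_threshold = 1000) {
  stopifnot(inherits(viewport, "viewport"))
  bpp <- viewport_span(viewport) / viewport$pixel_width
  if (bpp <= SEQUENCE_TIER_MAX_BPP) return(zoom_tier(bpp, "sequence"))
  if (bpp <= individual_threshold) return(zoom_tier(bpp, "individual"))
  zoom_tier(bpp, "summary", bin_width = 10^ceiling(log10(bpp)))
}

#' Tile a window with fixed-width bins
#'
#' Bins start at `window$start` and tile left to right; the last bin is
#' truncated at the window end rather than overhanging.
#'
#' @param window A [genomic_segment()].
#' @param bin_width Bin width in bp.
#' @return A data.frame with `bin_start`, `bin_stop`.
#' @export
bin_tiling <- function(window, bin_width) {
  if (bin_width < 1) stop_argument("bin_width must be >= 1")
  starts <- seq(window$start, window$stop, by = bin_width)
  data.frame(bin_start = starts,
             bin_stop = pmin(starts + bin_width - 1, window$stop))
}

#' Summarize features into fixed-width bins
#'
#' The binned representation used above the individual-feature zoom range:
#' per bin, the number of overlapping features (`count`, a feature counted
#' once in every bin it overlaps, preserving the visual mass of long features
#' at low zoom), the fraction of bin bases covered by at least one feature
#' (`coverage_fraction`), and the maximum score among overlapping scored
#' features (`max_score`, `NA` when none).
#'
#' @param features A [das_features()] table.
#' @param window A [genomic_segment()] to tile.
#' @param bin_width Bin width in bp (>= 1).
#' @return A `summary_bins` data.frame with columns `bin_start`, `bin_stop`,
#'   `count`, `coverage_fraction`, `max_score`.
#' @export
summarize_features <- function(features, window, bin_width) {
  stopifnot(inherits(window, "genomic_segment"))
  bins <- bin_tiling(window, bin_width)
  nb <- nrow(bins)
  bin_ir <- IRanges::IRanges(start = bins$bin_start, end = bins$bin_stop)
  if (nrow(features) == 0) {
    out <- data.frame(bins, count = integer(nb), coverage_fraction = numeric(nb),
                      max_score = rep(NA_real_, nb))
    class(out) <- c("summary_bins", "data.frame")
    return(out)
  }
  feat_ir <- IRanges::IRanges(start = features$start, end = features$stop)
  hits <- IRanges::findOverlaps(bin_ir, feat_ir)
  count <- IRanges::countOverlaps(bin_ir, feat_ir)
  max_score <- rep(NA_real_, nb)
  if (length(hits)) {
    sc <- features$score[S4Vectors_subjectHits(hits)]
    keep <- !is.na(sc)
    if (any(keep)) {
      agg <- tapply(sc[keep], S4Vectors_queryHits(hits)[keep], max)
      max_score[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  # union of feature bases per bin
  covered <- IRanges::reduce(feat_ir)
  inter <- IRanges::pintersect(IRanges::findOverlapPairs(bin_ir, covered))
  cov_bases <- numeric(nb)
  if (length(inter)) {
    ih <- IRanges::findOverlaps(bin_ir, covered)
    w <- IRanges::width(inter)
    agg <- tapply(w, S4Vectors_queryHits(ih), sum)
    cov_bases[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- data.frame(bins, count = as.integer(count),
                    coverage_fraction = cov_bases / (bins$bin_stop - bins$bin_start + 1),
                    max_score = max_score)
  class(out) <- c("summary_bins", "data.frame")
  out
}

S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' @export
print.summary_bins <- function(x, ...) {
  cat(sprintf("<summary_bins> %d bin(s), bin width %s bp\n", nrow(x),
              if (nrow(x)) format(x$bin_stop[1] - x$bin_start[1] + 1) else "?"))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Reduce a feature payload to a tier's granularity
#'
#' At sequence/individual tiers, returns the features overlapping the window,
#' unmodified (coordinates are never clipped here; clipping is a rendering
#' concern). At summary tier, returns [summarize_features()] bins. Data is
#' thereby only stored and transported at the required resolution.
#'
#' @param features A [das_features()] table.
#' @param tier A [zoom_tier()].
#' @param window A [genomic_segment()].
#' @return A `das_features` table or a `summary_bins` data.frame.
#' @export
reduce_payload <- function(features, tier, window) {
  stopifnot(inherits(tier, "zoom_tier"), inherits(window, "genomic_segment"))
  if (tier$kind == "summary")
    return(summarize_features(features, window, tier$bin_width))
  keep <- features$stop >= window$start & features$start <= window$stop
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
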