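# Viewport arithmetic. A viewport is a 1-based inclusive window on a segment
# drawn at a fixed pixel width. The pixel coordinate of a base is the left
# edge of its pixel cell: x = floor((pos - start) * pixel_width / span).
# This mapping is exactly invertible whenever span <= pixel_width (at least
# one pixel per base), which is what makes base-level views precise.

#' Define what to draw: a segment window at a pixel width
#'
#' @param segment_id Segment name.
#' @param start,stop 1-based inclusive window bounds.
#' @param pixel_width Width of the rendered area in pixels (>= 1).
#' @return An object of class `viewport`.
#' @export
viewport <- function(segment_id, start, stop, pixel_width = 1000) {
  if (!nzchar(segment_id)) stop_argument("segment_id must be non-empty")
  start <- as.numeric(start); stop <- as.numeric(stop)
  pixel_width <- as.numeric(pixel_width)
  if (is.na(start) || is.na(stop) || start > stop || start < 1)
    stop_argument("viewport needs 1 <= start <= stop")
  if (is.na(pixel_width) || pixel_width < 1)
    stop_argument("pixel_width must be >= 1")
  structure(list(segment_id = segment_id, start = start, stop = stop,
                 pixel_width = pixel_width), class = "viewport")
}

#' @export
print.viewport <- function(x, ...) {
  cat(sprintf("<viewport> %s:%s-%s @ %s px (%.4g bp/px)\n", x$segment_id,
              format(x$start, big.mark = ","), format(x$stop, big.mark = ","),
              format(x$pixel_width), viewport_span(x) / x$pixel_width))
  invisible(x)
}

viewport_span <- function(vp) vp$stop - vp$start + 1

viewport_segment <- function(vp)
  genomic_segment(vp$segment_id, vp$start, vp$stop)

#' Map a genomic position to a pixel x coordinate
#'
#' Returns the left edge of the position's pixel cell. Positions outside the
#' viewport map outside `[0, pixel_width - 1]`; no clamping is applied here
#' (clipping is the renderer's job).
#'
#' @param pos Genomic position(s), 1-based.
#' @param vp A [viewport()].
#' @return Integer pixel x coordinate(s).
#' @export
genome_to_pixel <- function(pos, vp) {
  span <- viewport_span(vp)
  floor((as.numeric(pos) - vp$start) * vp$pixel_width / span)
}

#' Map a pixel x coordinate back to a genomic position
#'
#' Inverse of [genome_to_pixel()]: recovers the position exactly whenever
#' the viewport has at least one pixel per base (`span <= pixel_width`).
#'
#' @param x Pixel x coordinate(s).
#' @param vp A [viewport()].
#' @return Genomic position(s).
#' @export
pixel_to_genome <- function(x, vp) {
  span <- viewport_span(vp)
  vp$start + floor(as.numeric(x) * span / vp$pixel_width)
}

# inclusive pixel extent [x1, x2] of genomic range [s, e] in the viewport,
# clipped to the canvas; each base gets its whole cell at high zoom.
# NULL when the range does not intersect the viewport.
pixel_extent <- function(s, e, vp) {
  s2 <- max(s, vp$start); e2 <- min(e, vp$stop)
  if (s2 > e2) return(NULL)
  span <- viewport_span(vp)
  x1 <- genome_to_pixel(s2, vp)
  x2 <- ceiling((e2 - vp$start + 1) * vp$pixel_width / span) - 1
  x1 <- max(0, x1); x2 <- min(vp$pixel_width - 1, max(x2, x1))
  c(x1, x2)
}

#' Choose ruler tick positions for a viewport
#'
#' The step is the smallest value in the 1-2-5 ladder (`{1,2,5} x 10^k`)
#' such that the window holds at most `target_ticks` steps; positions are the
#' multiples of the step inside the window.
#'
#' @param vp A [viewport()].
#' @param target_ticks Maximum number of ticks (>= 2, default 10).
#' @return List with `step` (bp) and `positions` (bp vector).
#' @export
tick_marks <- function(vp, target_ticks = 10) {
  if (target_ticks < 2) stop_argument("target_ticks must be >= 2")
  span <- viewport_span(vp)
  k <- 0
  repeat {
    for (m in c(1, 2, 5)) {
      step <- m * 10^k
      if (span / step <= target_ticks) {
        first <- ceiling(vp$start / step) * step
        positions <- if (first > vp$stop) numeric()
                     else seq(first, vp$stop, by = step)
        return(list(step = step, positions = positions))
      }
    }
    k <- k + 1
  }
}

#' Stack overlapping features into rows (bump layout)
#'
#' Greedy first-fit: features are sorted by (start, stop, feature_id) and
#' each takes the lowest row where its pixel extent clears the previous
#' occupant by at least `min_gap_px` pixels. Two features in one row never
#' overlap horizontally. Features that do not intersect the viewport get row
#' `NA`.
#'
#' @param features A [das_features()] table.
#' @param vp A [viewport()].
#' @param style A [track_style()] (supplies `min_gap_px`).
#' @return A `track_layout`: list with `row_of` (named integer vector,
#'   feature_id -> 0-based row) and `n_rows`.
#' @export
assign_rows <- function(features, vp, style = track_style()) {
  n <- nrow(features)
  ord <- order(features$start, features$stop, features$feature_id)
  row_of <- stats::setNames(rep(NA_integer_, n), features$feature_id)
  row_last <- numeric(0)   # rightmost occupied pixel per row
  gap <- style$min_gap_px
  for (i in ord) {
    ext <- pixel_extent(features$start[i], features$stop[i], vp)
    if (is.null(ext)) next
    placed <- FALSE
    if (length(row_last)) {
      for (r in seq_along(row_last)) {
        if (ext[1] - row_last[r] - 1 >= gap) {
          row_of[i] <- r - 1L
          row_last[r] <- ext[2]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      row_last <- c(row_last, ext[2])
      row_of[i] <- length(row_last) - 1L
    }
  }
  structure(list(row_of = row_of, n_rows = length(row_last)),
            class = "track_layout")
}

#' Derive a linked viewport from an existing one
#'
#' Linked track containers show an extended region ("next"/"previous"
#' neighbours at the same zoom) or the same region at another zoom level
#' (same center, scaled span). This is pure viewport arithmetic.
#'
#' @param vp A [viewport()].
#' @param role One of `"adjacent_next"`, `"adjacent_previous"`,
#'   `"same_region_other_zoom"`.
#' @param zoom_factor Span multiplier for `same_region_other_zoom`
#'   (e.g. 10 for a 10x wider context view).
#' @param segment_length Optional segment length to clamp against.
#' @return A new [viewport()] with the same pixel width.
#' @export
derive_viewport <- function(vp, role, zoom_factor = 10, segment_length = NA) {
  role <- match.arg(role, c("adjacent_next", "adjacent_previous",
                            "same_region_other_zoom"))
  span <- viewport_span(vp)
  if (role == "adjacent_next") {
    start <- vp$stop + 1; stop <- vp$stop + span
  } else if (role == "adjacent_previous") {
    start <- max(1, vp$start - span); stop <- vp$start - 1
    if (stop < start) stop_argument("no previous region: viewport starts at 1")
  } else {
    center <- (vp$start + vp$stop) / 2
    new_span <- max(1, round(span * zoom_factor))
    start <- max(1, round(center - (new_span - 1) / 2))
    stop <- start + new_span - 1
  }
  if (!is.na(segment_length)) {
    stop <- min(stop, segment_length)
    start <- min(start, stop)
  }
  viewport(vp$segment_id, start, stop, vp$pixel_width)
}
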