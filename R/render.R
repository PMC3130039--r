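# Track rendering. Each feature becomes one glyph on an image layer — the
# layer, not per-feature elements, is what moves when a view pans, which is
# what makes client-side rendering responsive. A track layer is the list of
# paint primitives for one track at one viewport; compose_view() stacks a
# ruler and the track layers into one document and writes SVG or PNG.

SEQUENCE_COLORS <- c(A = "#33A02C", C = "#1F78B4", G = "#FF7F00",
                     T = "#E31A1C", N = "#999999")

#' Render one track layer
#'
#' The payload kind must match the tier kind: a [das_features()] table for
#' an individual tier (drawn as one glyph per feature, stacked by `layout`),
#' a `summary_bins` table for a summary tier (drawn as a histogram of counts,
#' bar heights normalized to the window maximum so low-zoom views always
#' show structure), or residue text for a sequence tier (one centered letter
#' per base over per-feature glyphs' place). Glyphs crossing the viewport
#' edge are clipped to the canvas; output is deterministic for fixed inputs.
#'
#' @param payload Features, bins, or a residues string / [sequence_block()].
#' @param vp A [viewport()].
#' @param style A [track_style()].
#' @param tier The [zoom_tier()] the payload was reduced to; defaults to
#'   [choose_tier()] of the viewport.
#' @param layout Optional [assign_rows()] result (computed when absent).
#' @return A `track_layer`: list with `prims`, `width`, `height`.
#' @export
render_track <- function(payload, vp, style = track_style(),
                         tier = choose_tier(vp), layout = NULL) {
  stopifnot(inherits(vp, "viewport"))
  W <- vp$pixel_width
  H <- style$track_height
  prims <- list(prim_rect(0, 0, W, H, style$bg_color))

  is_bins <- inherits(payload, "summary_bins")
  is_seq <- is.character(payload) || inherits(payload, "sequence_block")
  if (is_bins && tier$kind != "summary")
    stop_argument("bin payload requires a summary tier")
  if (!is_bins && tier$kind == "summary")
    stop_argument("summary tier requires a bin payload")
  if (is_seq && tier$kind != "sequence")
    stop_argument("residue payload requires a sequence tier")

  if (is_seq) {
    residues <- if (inherits(payload, "sequence_block")) payload$residues
                else payload
    prims <- c(prims, sequence_prims(residues, vp, H))
  } else if (is_bins) {
    prims <- c(prims, histogram_prims(payload, vp, style))
  } else if (nrow(payload)) {
    if (is.null(layout)) layout <- assign_rows(payload, vp, style)
    prims <- c(prims, feature_prims(payload, vp, style, layout))
  }
  structure(list(prims = prims, width = W, height = H), class = "track_layer")
}

sequence_prims <- function(residues, vp, height) {
  span <- viewport_span(vp)
  if (nchar(residues) != span)
    stop_argument("residues length does not match viewport span")
  cell <- vp$pixel_width / span
  size <- max(7, min(height - 2, 14))
  bases <- strsplit(toupper(residues), "")[[1]]
  y <- max(0, (height - size) / 2)
  lapply(seq_along(bases), function(i) {
    col <- SEQUENCE_COLORS[[bases[i]]]
    if (is.null(col)) col <- "#000000"
    prim_text(genome_to_pixel(vp$start + i - 1, vp) + cell / 2, y,
              bases[i], size = size, fill = col, anchor = "middle")
  })
}

histogram_prims <- function(bins, vp, style) {
  if (!nrow(bins) || max(bins$count) == 0) return(list())
  maxc <- max(bins$count)
  avail <- style$track_height - 2
  out <- list()
  for (i in seq_len(nrow(bins))) {
    if (bins$count[i] == 0) next
    ext <- pixel_extent(bins$bin_start[i], bins$bin_stop[i], vp)
    if (is.null(ext)) next
    h <- max(1, round(avail * bins$count[i] / maxc))
    out[[length(out) + 1]] <- prim_rect(ext[1], style$track_height - 1 - h,
                                        ext[2] - ext[1] + 1, h, style$fg_color)
  }
  out
}

feature_prims <- function(features, vp, style, layout) {
  n <- nrow(features)
  out <- vector("list", 3L * n)
  k <- 0L
  put <- function(p) { k <<- k + 1L; out[[k]] <<- p }
  gh <- max(1, style$row_height - 2)
  rows <- unname(layout$row_of[features$feature_id])
  for (i in seq_len(n)) {
    row <- rows[i]
    if (is.na(row)) next
    y <- row * style$row_height + 1
    if (y + gh > style$track_height) next    # row band does not fit: clip
    ext <- pixel_extent(features$start[i], features$stop[i], vp)
    if (is.null(ext)) next
    w <- ext[2] - ext[1] + 1
    g <- style$glyph
    if (g == "arrow" && (features$orientation[i] == "unstranded" || w < 4))
      g <- "box"
    switch(g,
      box = ,
      histogram = put(prim_rect(ext[1], y, w, gh, style$fg_color)),
      tick = put(prim_rect(ext[1], y, 1, gh, style$fg_color)),
      line = put(prim_rect(ext[1], y + floor(gh / 2), w, 1, style$fg_color)),
      arrow = {
        ap <- arrow_prims(ext, y, gh, w, features$orientation[i],
                          style$fg_color)
        put(ap[[1]]); put(ap[[2]])
      }
    )
    if (style$show_labels && w >= 30) {
      lab <- if (!is.na(features$label[i])) features$label[i]
             else features$feature_id[i]
      size <- min(gh, 7)
      put(prim_text(ext[1] + 2, y + (gh - size) / 2, lab,
                    size = size, fill = "#000000"))
    }
  }
  out[seq_len(k)]
}

arrow_prims <- function(ext, y, gh, w, orientation, fill) {
  head <- min(gh, max(2, floor(w / 3)))
  if (orientation == "forward") {
    body <- prim_rect(ext[1], y, w - head, gh, fill)
    tip <- prim_polygon(c(ext[2] - head + 1, ext[2] + 1, ext[2] - head + 1),
                        c(y, y + gh / 2, y + gh), fill)
  } else {
    body <- prim_rect(ext[1] + head, y, w - head, gh, fill)
    tip <- prim_polygon(c(ext[1] + head, ext[1], ext[1] + head),
                        c(y, y + gh / 2, y + gh), fill)
  }
  list(body, tip)
}

#' Render the coordinate ruler for a viewport
#'
#' A baseline with [tick_marks()] ticks and position labels.
#'
#' @param vp A [viewport()].
#' @param height Ruler height in px.
#' @return A `track_layer`.
#' @export
ruler_layer <- function(vp, height = 20) {
  W <- vp$pixel_width
  prims <- list(prim_rect(0, 0, W, height, "#FFFFFF"),
                prim_rect(0, height - 2, W, 1, "#000000"))
  tm <- tick_marks(vp)
  for (p in tm$positions) {
    x <- genome_to_pixel(p, vp)
    if (x < 0 || x > W - 1) next
    prims <- c(prims, list(prim_rect(x, height - 7, 1, 5, "#000000")))
    lab <- format(p, big.mark = ",", scientific = FALSE, trim = TRUE)
    anchor <- if (x > W - 30) "end" else if (x < 30) "start" else "middle"
    prims <- c(prims, list(prim_text(x, 1, lab, size = 7, fill = "#000000",
                                     anchor = anchor)))
  }
  structure(list(prims = prims, width = W, height = height),
            class = "track_layer")
}

#' Declare one track of a view
#'
#' @param label Track label drawn in the composed image.
#' @param payload Features / bins / residues, already reduced to `tier`.
#' @param tier The [zoom_tier()] of the payload.
#' @param style A [track_style()].
#' @param segment_id Segment the payload belongs to; checked against the
#'   container's viewport.
#' @return A `view_track` list.
#' @export
view_track <- function(label, payload, tier, style = track_style(),
                       segment_id = NULL) {
  structure(list(label = label, payload = payload, tier = tier,
                 style = style, segment_id = segment_id),
            class = "view_track")
}

#' Compose tracks into a track-container image
#'
#' All tracks in one container share the container's viewport — the same
#' region at the same zoom level. The ruler is drawn on top, then the tracks
#' in declared order, each labeled; the total image height is the ruler
#' height plus the sum of the track heights.
#'
#' @param vp The container [viewport()].
#' @param tracks List of [view_track()]s.
#' @param path Output file; when `NULL` the document/raster is returned
#'   without writing.
#' @param format `"svg"` or `"png"`.
#' @param ruler_height Ruler height in px.
#' @return For SVG, the document text; for PNG, the raster array
#'   (height x width x 3). Written to `path` when given. Invisible when
#'   written.
#' @export
compose_view <- function(vp, tracks = list(), path = NULL,
                         format = c("svg", "png"), ruler_height = 20) {
  format <- match.arg(format)
  stopifnot(inherits(vp, "viewport"))
  for (tr in tracks) {
    if (!is.null(tr$segment_id) && tr$segment_id != vp$segment_id)
      stop_container(sprintf(
        "track '%s' is on segment %s but the container views %s",
        tr$label, tr$segment_id, vp$segment_id))
  }
  layers <- list(ruler_layer(vp, ruler_height))
  for (tr in tracks) {
    layer <- render_track(tr$payload, vp, tr$style, tier = tr$tier)
    if (nzchar(tr$label))
      layer$prims <- c(layer$prims,
                       list(prim_text(2, 1, tr$label, size = 7,
                                      fill = "#555555")))
    layers <- c(layers, list(layer))
  }
  prims <- list()
  y <- 0
  for (layer in layers) {
    prims <- c(prims, offset_prims(layer$prims, 0, y))
    y <- y + layer$height
  }
  total_height <- y
  if (format == "svg") {
    doc <- svg_document(prims, vp$pixel_width, total_height)
    if (!is.null(path)) {
      writeChar(doc, path, eos = NULL)
      return(invisible(doc))
    }
    return(doc)
  }
  arr <- raster_paint(prims, vp$pixel_width, total_height)
  if (!is.null(path)) {
    png::writePNG(arr, path)
    return(invisible(arr))
  }
  arr
}
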