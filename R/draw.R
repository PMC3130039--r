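# Drawing backend. render_track()/compose_view() emit a flat list of
# primitives (rect, polygon, text) in paint order; the same list is written
# either as an SVG document or painted into a pixel raster for PNG. Both
# paths are fully deterministic: numbers are formatted canonically in SVG,
# and the rasterizer uses only integer scanline arithmetic plus a built-in
# 5x7 bitmap font (no system font or graphics device is involved, so output
# is identical across machines and runs).

prim_rect <- function(x, y, w, h, fill) {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = toupper(fill))
}

prim_polygon <- function(xs, ys, fill) {
  list(kind = "polygon", xs = xs, ys = ys, fill = toupper(fill))
}

# (x, y) is the top-left corner of the text box; size is the glyph height in
# px; anchor one of "start", "middle", "end"
prim_text <- function(x, y, text, size = 10, fill = "#000000",
                      anchor = "start") {
  list(kind = "text", x = x, y = y, text = as.character(text), size = size,
       fill = toupper(fill), anchor = anchor)
}

offset_prims <- function(prims, dx, dy) {
  lapply(prims, function(p) {
    if (p$kind == "polygon") {
      p$xs <- p$xs + dx; p$ys <- p$ys + dy
    } else {
      p$x <- p$x + dx; p$y <- p$y + dy
    }
    p
  })
}

# ---- SVG ------------------------------------------------------------------

fmt_n <- function(x) format(round(x, 2), trim = TRUE, scientific = FALSE,
                            drop0trailing = TRUE)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_document <- function(prims, width, height) {
  body <- vapply(prims, function(p) {
    switch(p$kind,
      rect = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                     fmt_n(p$x), fmt_n(p$y), fmt_n(p$w), fmt_n(p$h), p$fill),
      polygon = sprintf('<polygon points="%s" fill="%s"/>',
                        paste(sprintf("%s,%s", fmt_n(p$xs), fmt_n(p$ys)),
                              collapse = " "), p$fill),
      text = sprintf(paste0('<text x="%s" y="%s" font-family="monospace" ',
                            'font-size="%s" fill="%s" text-anchor="%s">%s</text>'),
                     fmt_n(p$x), fmt_n(p$y + p$size), fmt_n(p$size), p$fill,
                     c(start = "start", middle = "middle", end = "end")[p$anchor],
                     xml_escape(p$text)),
      stop_argument(sprintf("unknown primitive kind '%s'", p$kind))
    )
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                        'height="%s" viewBox="0 0 %s %s">\n'),
                 fmt_n(width), fmt_n(height), fmt_n(width), fmt_n(height)),
         paste(body, collapse = "\n"),
         if (length(body)) "\n" else "", "</svg>\n")
}

# ---- raster ---------------------------------------------------------------

hex_to_rgb <- function(hex) {
  hex <- sub("^#", "", hex)
  c(strtoi(substr(hex, 1, 2), 16L), strtoi(substr(hex, 3, 4), 16L),
    strtoi(substr(hex, 5, 6), 16L)) / 255
}

raster_new <- function(width, height, bg = "#FFFFFF") {
  arr <- array(0, dim = c(height, width, 3))
  col <- hex_to_rgb(bg)
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

# Each primitive is resolved to the set of (0-based) pixel coordinates it
# covers; painting is a single indexed assignment per primitive, so the
# image array is modified in place inside raster_paint (no per-glyph copies).

# even-odd scanline rasterization at pixel centers
polygon_pixels <- function(xs, ys) {
  n <- length(xs)
  y_lo <- floor(min(ys)); y_hi <- ceiling(max(ys))
  py_out <- integer(); px_out <- integer()
  for (py in y_lo:y_hi) {
    yc <- py + 0.5
    crossings <- numeric()
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ys[i]; y2 <- ys[j]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        t <- (yc - y1) / (y2 - y1)
        crossings <- c(crossings, xs[i] + t * (xs[j] - xs[i]))
      }
    }
    crossings <- sort(crossings)
    k <- 1
    while (k + 1 <= length(crossings)) {
      x1 <- ceiling(crossings[k] - 0.5)
      x2 <- floor(crossings[k + 1] - 0.5)
      if (x2 >= x1) {
        px_out <- c(px_out, x1:x2)
        py_out <- c(py_out, rep.int(py, x2 - x1 + 1))
      }
      k <- k + 2
    }
  }
  list(x = px_out, y = py_out)
}

text_pixels <- function(x, y, text, size, anchor = "start") {
  scale <- max(1L, round(size / 7))
  chars <- strsplit(toupper(text), "")[[1]]
  cw <- 6L * scale
  total_w <- length(chars) * cw
  x0 <- floor(switch(anchor, start = x, middle = x - total_w / 2,
                     end = x - total_w))
  y0 <- floor(y)
  xs <- integer(); ys <- integer()
  for (ci in seq_along(chars)) {
    glyph <- FONT5X7[[chars[ci]]]
    if (is.null(glyph)) glyph <- FONT5X7[["?"]]
    bits <- matrix(unlist(strsplit(glyph, "")) == "#", nrow = 7, byrow = TRUE)
    idx <- which(bits, arr.ind = TRUE)
    if (!nrow(idx)) next
    for (sy in seq_len(scale) - 1L) {
      for (sx in seq_len(scale) - 1L) {
        ys <- c(ys, y0 + (idx[, 1] - 1L) * scale + sy)
        xs <- c(xs, x0 + (ci - 1L) * cw + (idx[, 2] - 1L) * scale + sx)
      }
    }
  }
  list(x = xs, y = ys)
}

raster_paint <- function(prims, width, height, bg = "#FFFFFF") {
  W <- as.integer(width); H <- as.integer(height)
  arr <- raster_new(W, H, bg)
  for (p in prims) {
    col <- hex_to_rgb(p$fill)
    if (p$kind == "rect") {
      x1 <- max(0, floor(p$x)); y1 <- max(0, floor(p$y))
      x2 <- min(W - 1, ceiling(p$x + p$w) - 1)
      y2 <- min(H - 1, ceiling(p$y + p$h) - 1)
      if (x2 >= x1 && y2 >= y1)
        for (ch in 1:3) arr[(y1:y2) + 1L, (x1:x2) + 1L, ch] <- col[ch]
      next
    }
    px <- switch(p$kind,
      polygon = polygon_pixels(p$xs, p$ys),
      text = text_pixels(p$x, p$y, p$text, p$size, p$anchor),
      stop_argument(sprintf("unknown primitive kind '%s'", p$kind))
    )
    keep <- px$x >= 0 & px$x < W & px$y >= 0 & px$y < H
    if (!any(keep)) next
    xi <- px$x[keep] + 1L; yi <- px$y[keep] + 1L
    for (ch in 1:3) arr[cbind(yi, xi, ch)] <- col[ch]
  }
  arr
}

# 5x7 bitmap font ('#' = set). Covers what track labels, rulers and sequence
# rows need; anything else renders as '?'.
FONT5X7 <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#..##", "#.#.#", "##..#", "#...#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  "," = c(".....", ".....", ".....", ".....", ".....", "..#..", ".#..."),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "-" = c(".....", ".....", ".....", ".###.", ".....", ".....", "....."),
  "_" = c(".....", ".....", ".....", ".....", ".....", ".....", "#####"),
  "+" = c(".....", "..#..", "..#..", "#####", "..#..", "..#..", "....."),
  "|" = c("..#..", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "/" = c("....#", "...#.", "...#.", "..#..", ".#...", ".#...", "#...."),
  "(" = c("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#."),
  ")" = c(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#..."),
  "'" = c("..#..", "..#..", ".....", ".....", ".....", ".....", "....."),
  "?" = c(".###.", "#...#", "....#", "...#.", "..#..", ".....", "..#.."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)
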