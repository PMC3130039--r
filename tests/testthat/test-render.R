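# Coordinate mapping, bump layout, ruler, glyph rendering, composition

test_that("genome_to_pixel maps endpoints per the left-edge formula", {
  vp <- viewport("c", 1, 1000, 1000)
  expect_equal(genome_to_pixel(1, vp), 0)
  expect_equal(genome_to_pixel(1000, vp), 999)
  vp2 <- viewport("c", 1, 10, 100)
  expect_equal(genome_to_pixel(5, vp2), 40)
  # no clamping: outside positions map outside the canvas
  expect_lt(genome_to_pixel(0, vp), 0)
  expect_gte(genome_to_pixel(1001, vp), 1000)
})

test_that("pixel mapping is exactly invertible at base-level zoom", {
  for (vp in list(viewport("c", 1, 100, 100), viewport("c", 50, 949, 1800),
                  viewport("c", 7, 7, 13))) {
    pos <- vp$start:vp$stop
    expect_equal(pixel_to_genome(genome_to_pixel(pos, vp), vp), pos)
  }
})

test_that("tick_marks picks the smallest 1-2-5 step meeting the budget", {
  tm <- tick_marks(viewport("c", 1, 1000, 1000), 10)
  expect_equal(tm$step, 100)
  expect_equal(tm$positions, seq(100, 1000, by = 100))

  tm2 <- tick_marks(viewport("c", 1, 1234, 1000), 10)
  # oracle: enumerate candidate steps, pick the smallest satisfying the bound
  cand <- sort(as.vector(outer(c(1, 2, 5), 10^(0:6))))
  expect_equal(tm2$step, cand[which(1234 / cand <= 10)[1]])
  expect_equal(tm2$positions, seq(200, 1200, by = 200))

  tm3 <- tick_marks(viewport("c", 5, 5, 100), 10)
  expect_equal(tm3$step, 1)
  expect_equal(tm3$positions, 5)
})

test_that("disjoint features share row 0; mutual overlaps stack by pigeonhole", {
  vp <- viewport("c", 1, 1000, 1000)
  style <- track_style(min_gap_px = 2)
  disjoint <- das_features(feature_id = c("a", "b", "c"),
                           start = c(1, 400, 800), stop = c(100, 500, 900),
                           type_id = "t")
  lay <- assign_rows(disjoint, vp, style)
  expect_equal(unname(lay$row_of), c(0L, 0L, 0L))
  expect_equal(lay$n_rows, 1L)

  nested <- das_features(feature_id = c("a", "b", "c"),
                         start = c(1, 50, 100), stop = c(500, 550, 600),
                         type_id = "t")
  lay2 <- assign_rows(nested, vp, style)
  expect_equal(sort(unname(lay2$row_of)), 0:2)
})

test_that("bump layout matches an independent first-fit oracle with no collisions", {
  g <- tiny_genome(42, seg_len = 1e5)
  feats <- g$segments$chr1$features
  vp <- viewport("chr1", 1, 1e5, 1000)
  for (gap in c(0, 2, 5)) {
    style <- track_style(min_gap_px = gap)
    lay <- assign_rows(feats, vp, style)
    expect_equal(lay$row_of, oracle_first_fit(feats, vp, gap))
    # pairwise: no same-row horizontal overlap, gap respected
    ext <- t(vapply(seq_len(nrow(feats)), function(i)
      dastrack:::pixel_extent(feats$start[i], feats$stop[i], vp), numeric(2)))
    for (r in unique(stats::na.omit(lay$row_of))) {
      in_row <- which(lay$row_of[feats$feature_id] == r)
      e <- ext[in_row, , drop = FALSE]
      e <- e[order(e[, 1]), , drop = FALSE]
      if (nrow(e) > 1)
        expect_true(all(e[-1, 1] - e[-nrow(e), 2] - 1 >= gap))
    }
  }
})

test_that("an empty payload renders to a pure-background layer", {
  vp <- viewport("c", 1, 1000, 500)
  style <- track_style(track_height = 40, bg_color = "#EEEEFF")
  layer <- render_track(das_features(), vp, style)
  arr <- dastrack:::raster_paint(layer$prims, layer$width, layer$height)
  expect_equal(dim(arr), c(40, 500, 3))
  bg <- dastrack:::hex_to_rgb("#EEEEFF")
  for (ch in 1:3) expect_true(all(arr[, , ch] == bg[ch]))
})

test_that("a single glyph occupies exactly its predicted pixel extent", {
  vp <- viewport("c", 1, 1000, 1000)
  f <- das_features(feature_id = "f", start = 401, stop = 500, type_id = "t")
  style <- track_style(glyph = "box", track_height = 20, row_height = 12,
                       fg_color = "#FF0000")
  layer <- render_track(f, vp, style)
  arr <- dastrack:::raster_paint(layer$prims, layer$width, layer$height)
  non_bg <- which(arr[, , 1] != 1 | arr[, , 2] != 1 | arr[, , 3] != 1,
                  arr.ind = TRUE)
  xs <- sort(unique(non_bg[, 2])) - 1   # 0-based pixel columns
  expect_equal(min(xs), genome_to_pixel(401, vp))
  expect_equal(range(xs), c(400, 499))
})

test_that("glyphs crossing the viewport edge are clipped to the canvas", {
  vp <- viewport("c", 101, 200, 100)
  f <- das_features(feature_id = c("l", "r"), start = c(50, 180),
                    stop = c(120, 400), type_id = "t")
  layer <- render_track(f, vp, track_style(track_height = 30))
  for (p in layer$prims) {
    if (p$kind == "rect") {
      expect_gte(p$x, 0)
      expect_lte(p$x + p$w, 100)
    }
  }
})

test_that("rendering is deterministic: identical calls give identical SVG bytes", {
  g <- tiny_genome(3, seg_len = 2e4)
  vp <- viewport("chr1", 1, 2e4, 800)
  tier <- choose_tier(vp)
  tr <- view_track("features", g$segments$chr1$features, tier,
                   track_style(glyph = "arrow"), "chr1")
  s1 <- compose_view(vp, list(tr))
  s2 <- compose_view(vp, list(tr))
  expect_identical(s1, s2)
  a1 <- compose_view(vp, list(tr), format = "png")
  a2 <- compose_view(vp, list(tr), format = "png")
  expect_identical(a1, a2)
})

test_that("composed image height is ruler plus the sum of track heights", {
  vp <- viewport("c", 1, 1000, 300)
  t1 <- view_track("a", das_features(), zoom_tier(10, "individual"),
                   track_style(track_height = 40))
  t2 <- view_track("b", das_features(), zoom_tier(10, "individual"),
                   track_style(track_height = 60))
  arr <- compose_view(vp, list(t1, t2), format = "png", ruler_height = 20)
  expect_equal(dim(arr)[1], 120)
  # zero tracks: ruler-only image
  ruler_only <- compose_view(vp, list(), format = "png", ruler_height = 20)
  expect_equal(dim(ruler_only)[1], 20)
  svg <- compose_view(vp, list(t1, t2), ruler_height = 20)
  expect_match(svg, 'height="120"', fixed = TRUE)
})

test_that("a track on another segment is rejected by the container", {
  vp <- viewport("chr1", 1, 1000, 100)
  tr <- view_track("x", das_features(), zoom_tier(10, "individual"),
                   track_style(), segment_id = "chr2")
  expect_error(compose_view(vp, list(tr)), class = "das_container_error")
})

test_that("summary payloads render as a histogram with per-window normalization", {
  window <- genomic_segment("c", 1, 10000)
  feats <- das_features(feature_id = sprintf("f%d", 1:30),
                        start = rep(c(100, 5000, 5100), 10),
                        stop = rep(c(200, 5050, 5200), 10), type_id = "t")
  bins <- summarize_features(feats, window, 1000)
  vp <- viewport("c", 1, 10000, 100)
  layer <- render_track(bins, vp, track_style(track_height = 50),
                        tier = zoom_tier(2000, "summary", 1000))
  bars <- Filter(function(p) p$kind == "rect", layer$prims)[-1]  # drop bg
  expect_gte(length(bars), 2)
  # the densest bin reaches (almost) full height
  expect_equal(max(vapply(bars, `[[`, numeric(1), "h")), 48)
  # payload/tier mismatches are argument errors
  expect_error(render_track(bins, vp, track_style(),
                            tier = zoom_tier(10, "individual")),
               class = "das_argument_error")
  expect_error(render_track(feats, vp, track_style(),
                            tier = zoom_tier(2000, "summary", 1000)),
               class = "das_argument_error")
})

test_that("sequence tier draws one letter per base", {
  vp <- viewport("c", 11, 20, 100)
  layer <- render_track("ACGTACGTAC", vp, track_style(track_height = 16),
                        tier = zoom_tier(0.1, "sequence"))
  texts <- Filter(function(p) p$kind == "text", layer$prims)
  expect_length(texts, 10)
  expect_identical(vapply(texts, `[[`, "", "text"),
                   strsplit("ACGTACGTAC", "")[[1]])
})

test_that("derived viewports implement linked-view arithmetic", {
  vp <- viewport("chr1", 100001, 110000, 1000)
  nxt <- derive_viewport(vp, "adjacent_next")
  expect_equal(c(nxt$start, nxt$stop), c(110001, 120000))
  prv <- derive_viewport(vp, "adjacent_previous")
  expect_equal(c(prv$start, prv$stop), c(90001, 100000))
  ctx <- derive_viewport(vp, "same_region_other_zoom", zoom_factor = 10)
  expect_equal(ctx$stop - ctx$start + 1, 100000)
  expect_equal((ctx$start + ctx$stop) / 2, (vp$start + vp$stop) / 2)
})
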