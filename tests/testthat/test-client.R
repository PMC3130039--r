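# High-level client: tiered fetching through the cache, timeout surfacing

test_that("repeated fetches of the same window fetch zero new bases", {
  g <- tiny_genome(42)
  client <- das_client(transport = mock_transport(g, "http://m/das/mock"))
  src <- das_source_ref("http://m/das/mock")
  tier <- choose_tier(viewport("chr1", 1, 5e4, 1000))
  f1 <- client_fetch(client, src, "chr1", 1, 5e4, tier)
  fetched_once <- client$cache$stats$fetched_bases
  expect_gt(fetched_once, 0)
  f2 <- client_fetch(client, src, "chr1", 1, 5e4, tier)
  expect_equal(client$cache$stats$fetched_bases, fetched_once)
  expect_equal(f1, f2)
})

test_that("panning fetches only the missing flank", {
  g <- tiny_genome(42)
  client <- das_client(transport = mock_transport(g, "http://m/das/mock"))
  src <- das_source_ref("http://m/das/mock")
  tier <- choose_tier(viewport("chr1", 1, 2e4, 1000))
  client_fetch(client, src, "chr1", 1, 2e4, tier)
  before <- client$cache$stats$fetched_bases
  client_fetch(client, src, "chr1", 10001, 3e4, tier)
  expect_equal(client$cache$stats$fetched_bases - before, 1e4)
})

test_that("client assembly equals a direct one-shot fetch", {
  g <- tiny_genome(8)
  client <- das_client(transport = mock_transport(g, "http://m/das/mock"))
  src <- das_source_ref("http://m/das/mock")
  tier <- zoom_tier(100, "individual")
  # fetch in three overlapping pieces, then assemble the union window
  client_fetch(client, src, "chr1", 1, 30000, tier)
  client_fetch(client, src, "chr1", 25000, 60000, tier)
  client_fetch(client, src, "chr1", 60001, 100000, tier)
  got <- client_fetch(client, src, "chr1", 1, 1e5, tier)
  all_f <- g$segments$chr1$features
  expect_features_equal(got, all_f)
})

test_that("summary windows are snapped to the bin grid and reused across zooms", {
  g <- tiny_genome(4, seg_len = 1e6,
                   classes = list(feature_class("x", 500, 100, 1000)))
  client <- das_client(transport = mock_transport(g, "http://m/das/mock"))
  src <- das_source_ref("http://m/das/mock")
  tier <- zoom_tier(1500, "summary", bin_width = 10000)
  bins <- client_fetch(client, src, "chr1", 15000, 985000, tier)
  expect_s3_class(bins, "summary_bins")
  expect_equal(bins$bin_start[1], 10001)   # snapped down to the grid
  expect_equal(utils::tail(bins$bin_stop, 1), 990000)
  before <- client$cache$stats$fetched_bases
  # a second, narrower request at the same tier is served from cache
  client_fetch(client, src, "chr1", 200001, 400000, tier)
  expect_equal(client$cache$stats$fetched_bases, before)
})

test_that("the full pipeline renders all three tiers offline", {
  g <- tiny_genome(42)
  client <- das_client(transport = mock_transport(g, "http://m/das/mock"))
  src <- das_source_ref("http://m/das/mock")
  dir <- withr::local_tempdir()
  seq_png <- file.path(dir, "seq.png")
  ind_svg <- file.path(dir, "ind.svg")
  sum_svg <- file.path(dir, "sum.svg")
  i1 <- client_render(client, src, "chr1", 101, 180, 1000, path = seq_png,
                      format = "png")
  expect_identical(i1$tier$kind, "sequence")
  i2 <- client_render(client, src, "chr1", 1, 5e4, 1000, path = ind_svg)
  expect_identical(i2$tier$kind, "individual")
  i3 <- client_render(client, src, "chr1", 1, 1e5, 50, path = sum_svg)
  expect_identical(i3$tier$kind, "summary")
  for (p in c(seq_png, ind_svg, sum_svg)) expect_gt(file.size(p), 0)
  # heights advertised match the composed documents
  expect_match(readLines(ind_svg, n = 2)[2],
               sprintf('height="%d"', i2$height), fixed = TRUE)
})

test_that("HTTP timeouts surface as retryable errors, other failures as network errors", {
  err <- tryCatch(http_get("http://127.0.0.1:1/x", timeout_seconds = 1),
                  error = identity)
  expect_s3_class(err, "das_error")
  expect_false(is_retryable_error(err))
  cond <- tryCatch(dastrack:::stop_timeout("synthetic slow response"),
                   error = identity)
  expect_s3_class(cond, "das_timeout_error")
  expect_true(is_retryable_error(cond))
})

test_that("style overrides and per-category defaults reach the rendered tracks", {
  cfg <- default_config()
  expect_identical(style_for_category(cfg, "transcription")$glyph, "arrow")
  expect_identical(style_for_category(cfg, "unheard_of")$glyph,
                   cfg$styles$default$glyph)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("individual_threshold: 500",
               "styles:",
               "  transcription:",
               "    fg_color: '#112233'"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$individual_threshold, 500)
  expect_identical(cfg2$styles$transcription$fg_color, "#112233")
  expect_identical(cfg2$styles$transcription$glyph, "arrow")  # inherited
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("cache_ttl_seconds: -5", path2)
  expect_error(read_config(path2), class = "das_validation_error")
})
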