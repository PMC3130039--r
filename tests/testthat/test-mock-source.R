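# Synthetic genome generator and DAS server behaviour

test_that("generation is deterministic under a fixed seed", {
  a <- tiny_genome(42)
  b <- tiny_genome(42)
  expect_equal(a$segments$chr1$features, b$segments$chr1$features)
  expect_identical(a$segments$chr1$residues, b$segments$chr1$residues)
  c_ <- tiny_genome(43)
  expect_false(identical(a$segments$chr1$features, c_$segments$chr1$features))
})

test_that("every generated feature respects segment bounds and class counts", {
  spec <- mock_genome_spec(seed = 9, segments = c(chr1 = 1e6),
                           classes = list(feature_class("big", 1000, 100,
                                                        90000)))
  g <- generate_annotation_set(spec, with_residues = FALSE)
  f <- g$segments$chr1$features
  expect_equal(nrow(f), 1000)
  expect_true(all(f$start >= 1))
  expect_true(all(f$start <= f$stop))
  expect_true(all(f$stop <= 1e6))
})

test_that("scores, strands and groups follow the class definition", {
  g <- tiny_genome(11)
  f <- g$segments$chr1$features
  gene <- f[f$type_id == "gene", ]
  expect_true(all(gene$orientation %in% c("forward", "reverse")))
  expect_true(all(is.na(gene$score)))
  expect_equal(mean(!is.na(gene$group_id)), 0.5, tolerance = 0.05)
  grp_sizes <- table(stats::na.omit(gene$group_id))
  expect_true(all(grp_sizes >= 1 & grp_sizes <= 5))
  rep_ <- f[f$type_id == "repeat", ]
  expect_true(all(rep_$orientation == "unstranded"))
  expect_true(all(rep_$score >= 0 & rep_$score <= 1))
})

test_that("log-uniform lengths match the closed-form mean within 3 SE", {
  set.seed(1)
  a <- 100; b <- 10000; n <- 1e4
  draws <- rloguniform(n, a, b)
  expect_true(all(draws >= a & draws <= b))
  m <- (b - a) / log(b / a)           # ~2149.6
  expect_equal(m, 2149.6, tolerance = 1e-4)
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - m), 3 * se)
})

test_that("the generator consumes one RNG stream and leaves the caller's RNG alone", {
  set.seed(123)
  before <- .Random.seed
  invisible(tiny_genome(5, seg_len = 1000))
  expect_identical(.Random.seed, before)
})

test_that("emitted XML always parses and refuses invalid residue lengths", {
  g <- tiny_genome(13, seg_len = 2000)
  s <- g$segments$chr1
  expect_no_error(xml2::read_xml(emit_features_xml(s$segment, s$features)))
  expect_no_error(xml2::read_xml(emit_sources_xml(g$spec)))
  expect_no_error(xml2::read_xml(emit_entry_points_xml(g$spec)))
  expect_no_error(xml2::read_xml(emit_types_xml(g)))
  expect_error(emit_sequence_xml(s$segment, "ACGT"),
               class = "das_validation_error")
})

test_that("special characters in feature fields survive the XML round trip", {
  seg <- genomic_segment("chr1", 1, 100)
  f <- das_features(feature_id = "f<1>", label = "a & b \"quoted\"",
                    start = 1, stop = 10, type_id = "ty>pe",
                    notes = list(c("note <with> markup & stuff")))
  out <- parse_features(emit_features_xml(seg, f))
  expect_features_equal(out$features, f)
})

test_that("range queries return exactly the overlapping features (in-process)", {
  g <- tiny_genome(21)
  tr <- mock_transport(g, "http://m/das/mock")
  resp <- tr("http://m/das/mock/features?segment=chr1:20000,40000")
  expect_equal(resp$status, 200L)
  got <- parse_features(resp$body)$features
  all_f <- g$segments$chr1$features
  want <- all_f[all_f$stop >= 20000 & all_f$start <= 40000, ]
  expect_features_equal(got, want)

  # unknown segment: DAS error document, not an empty success
  bad <- tr("http://m/das/mock/features?segment=nope")
  expect_equal(bad$status, 200L)
  expect_error(parse_features(bad$body), class = "das_schema_error")
  # malformed range
  expect_equal(tr("http://m/das/mock/features?segment=chr1:50,10")$status, 400L)
})

test_that("the HTTP server answers the DAS command set end to end", {
  skip_if_not_installed("processx")
  spec <- tiny_spec(seed = 33, seg_len = 5e4)
  srv <- start_mock_das_server(spec)
  withr::defer(stop_mock_das_server(srv))
  g <- generate_annotation_set(spec)

  src <- parse_sources(http_get(paste0(srv$base_url, "/sources"))$body)[[1]]
  expect_identical(src$base_url, srv$base_url)

  ep <- parse_entry_points(http_get(paste0(srv$base_url, "/entry_points"))$body)
  expect_identical(ep$segment_id, "chr1")
  expect_equal(ep$total_length, 5e4)

  feats <- parse_features(das_fetch(src, "features", "chr1", 1000, 9000))
  local <- g$segments$chr1$features
  want <- local[local$stop >= 1000 & local$start <= 9000, ]
  expect_features_equal(feats$features, want)

  blk <- parse_sequence(das_fetch(src, "sequence", "chr1", 11, 40))
  expect_identical(blk$residues, substr(g$segments$chr1$residues, 11, 40))

  expect_equal(http_get(paste0(srv$base_url, "/stylesheet"))$status, 400L)
  expect_error(http_get("http://127.0.0.1:1/sources"),
               class = "das_network_error")
})
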