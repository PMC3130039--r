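# DAS request grammar and XML parsing

test_that("build_request follows the DAS request grammar", {
  src <- das_source_ref("http://example.org/das/hg19",
                        capabilities = c("features", "sequence",
                                         "entry_points"))
  expect_identical(build_request(src, "features", "1", 100, 200),
                   "http://example.org/das/hg19/features?segment=1:100,200")
  expect_identical(build_request(src, "entry_points"),
                   "http://example.org/das/hg19/entry_points")
  # trailing-slash normalization is idempotent
  src2 <- das_source_ref("http://example.org/das/hg19/",
                         capabilities = "sequence")
  expect_identical(build_request(src2, "sequence", "X"),
                   "http://example.org/das/hg19/sequence?segment=X")
})

test_that("build_request rejects bad commands and ranges", {
  src <- das_source_ref("http://example.org/das/hg19",
                        capabilities = "features")
  expect_error(build_request(src, "stylesheet"), class = "das_capability_error")
  expect_error(build_request(src, "features", start = 1, stop = 10),
               class = "das_argument_error")
  expect_error(build_request(src, "features", "1", 200, 100),
               class = "das_argument_error")
})

test_that("parse_features maps a hand-written document onto the model", {
  xml <- paste0(
    '<DASGFF><GFF version="1.0" href="x">',
    '<SEGMENT id="chr1" start="1" stop="1000" version="7">',
    '<FEATURE id="f1" label="first">',
    '<TYPE id="exon" category="transcription">exon</TYPE>',
    '<METHOD id="pred">pred</METHOD>',
    "<START>5</START><END>10</END>",
    "<SCORE>0.25</SCORE><ORIENTATION>+</ORIENTATION><PHASE>2</PHASE>",
    '<GROUP id="g1"/><LINK href="http://x/f1"/>',
    "<NOTE>a note</NOTE><NOTE>another</NOTE>",
    "<SOMEEXTENSION>ignored</SOMEEXTENSION>",
    "</FEATURE></SEGMENT></GFF></DASGFF>")
  out <- parse_features(xml)
  expect_identical(out$segment$segment_id, "chr1")
  expect_identical(out$segment$version, "7")
  f <- out$features
  expect_equal(nrow(f), 1)
  expect_identical(f$feature_id, "f1")
  expect_equal(f$start, 5)
  expect_equal(f$stop, 10)
  expect_identical(f$type_id, "exon")
  expect_identical(f$orientation, "forward")
  expect_equal(f$phase, 2L)
  expect_equal(f$score, 0.25)
  expect_identical(f$group_id, "g1")
  expect_identical(f$notes[[1]], c("a note", "another"))
})

test_that("parse_features handles empty documents and reports errors", {
  empty <- emit_features_xml(genomic_segment("chr9", 1, 500), das_features())
  out <- parse_features(empty)
  expect_equal(nrow(out$features), 0)
  expect_identical(out$segment$segment_id, "chr9")

  expect_error(parse_features("<DASGFF><GFF>no segment</GFF></DASGFF>"),
               class = "das_schema_error")
  expect_error(parse_features("<DASGFF><unclosed"), class = "das_parse_error")
})

test_that("a record with stop < start is rejected without blanking the track", {
  xml <- paste0(
    '<DASGFF><GFF version="1.0" href="x"><SEGMENT id="c" start="1" stop="100">',
    '<FEATURE id="good"><TYPE id="t">t</TYPE><START>1</START><END>10</END></FEATURE>',
    '<FEATURE id="bad"><TYPE id="t">t</TYPE><START>50</START><END>40</END></FEATURE>',
    "</SEGMENT></GFF></DASGFF>")
  expect_warning(out <- parse_features(xml), "bad")
  expect_identical(out$features$feature_id, "good")
  expect_identical(attr(out$features, "rejected"), "bad")
})

test_that("features round-trip through the emitter, field by field", {
  for (seed in c(7, 42)) {
    g <- tiny_genome(seed)
    seg <- g$segments$chr1
    out <- parse_features(emit_features_xml(seg$segment, seg$features))
    expect_features_equal(out$features, seg$features)
    expect_equal(out$segment$start, seg$segment$start)
    expect_equal(out$segment$stop, seg$segment$stop)
  }
})

test_that("parse_sources reads both SOURCES and legacy DSN dialects", {
  spec <- tiny_spec()
  srcs <- parse_sources(emit_sources_xml(spec, "http://h/das/mock"))
  expect_length(srcs, 1)
  expect_identical(srcs[[1]]$base_url, "http://h/das/mock")
  expect_true(all(c("features", "sequence", "entry_points") %in%
                    srcs[[1]]$capabilities))
  expect_identical(srcs[[1]]$coordinate_system, "synthetic-1.0")

  dsn <- paste0("<DASDSN><DSN>",
                '<SOURCE id="s1">First source</SOURCE>',
                "<MAPMASTER>http://a/das/one</MAPMASTER></DSN>",
                '<DSN><SOURCE id="s2">Second</SOURCE>',
                "<MAPMASTER>http://b/das/two</MAPMASTER></DSN></DASDSN>")
  out <- parse_sources(dsn)
  expect_length(out, 2)
  expect_identical(vapply(out, `[[`, "", "base_url"),
                   c("http://a/das/one", "http://b/das/two"))
  expect_length(parse_sources("<DASDSN></DASDSN>"), 0)
  expect_error(parse_sources("<WHAT/>"), class = "das_schema_error")
})

test_that("parse_sequence round-trips and enforces the length invariant", {
  seg <- genomic_segment("1", 1, 4)
  blk <- parse_sequence(paste0(
    '<DASSEQUENCE><SEQUENCE id="1" start="1" stop="4" version="1">',
    "ACGT</SEQUENCE></DASSEQUENCE>"))
  expect_identical(blk$residues, "ACGT")
  expect_equal(segment_span(blk$segment), 4)

  g <- tiny_genome(7, seg_len = 2000)
  s <- g$segments$chr1
  rt <- parse_sequence(emit_sequence_xml(s$segment, s$residues))
  expect_identical(rt$residues, s$residues)

  expect_error(parse_sequence(paste0(
    '<DASSEQUENCE><SEQUENCE id="1" start="1" stop="4">',
    "ACG</SEQUENCE></DASSEQUENCE>")), class = "das_validation_error")
})

test_that("entry points list the configured segments with lengths", {
  spec <- tiny_spec()
  ep <- parse_entry_points(emit_entry_points_xml(spec))
  expect_identical(ep$segment_id, "chr1")
  expect_equal(ep$total_length, unname(spec$segments[["chr1"]]))
})

test_that("case of residues is preserved through sequence parsing", {
  blk <- parse_sequence(paste0(
    '<DASSEQUENCE><SEQUENCE id="1" start="1" stop="6">',
    "AcGtNn</SEQUENCE></DASSEQUENCE>"))
  expect_identical(blk$residues, "AcGtNn")
})
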