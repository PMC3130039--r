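# Shared fixtures and independent oracles. The oracles deliberately use the
# dumbest correct algorithm (per-base bitmaps, double loops, re-sorting)
# so they share no code path with the implementation they check.

# small deterministic genome used across tests
tiny_spec <- function(seed = 42, seg_len = 1e5,
                      classes = list(
                        feature_class("gene", 60, 500, 20000, stranded = TRUE,
                                      grouped_fraction = 0.5,
                                      type_category = "transcription"),
                        feature_class("repeat", 120, 100, 2000, scored = TRUE,
                                      type_category = "repeat_region"),
                        feature_class("snv", 80, 1, 1, scored = TRUE,
                                      type_category = "variation"))) {
  mock_genome_spec(seed = seed, segments = c(chr1 = seg_len),
                   classes = classes)
}

tiny_genome <- function(seed = 42, ...) {
  generate_annotation_set(tiny_spec(seed = seed, ...))
}

# brute-force bin summary: double loop over (feature, bin) overlap tests
oracle_summarize <- function(features, window, bin_width) {
  starts <- seq(window$start, window$stop, by = bin_width)
  stops <- pmin(starts + bin_width - 1, window$stop)
  count <- integer(length(starts))
  max_score <- rep(NA_real_, length(starts))
  coverage <- numeric(length(starts))
  for (b in seq_along(starts)) {
    covered <- logical(stops[b] - starts[b] + 1)
    for (i in seq_len(nrow(features))) {
      if (features$stop[i] >= starts[b] && features$start[i] <= stops[b]) {
        count[b] <- count[b] + 1L
        s <- max(features$start[i], starts[b]) - starts[b] + 1
        e <- min(features$stop[i], stops[b]) - starts[b] + 1
        covered[s:e] <- TRUE
        if (!is.na(features$score[i]))
          max_score[b] <- max(max_score[b], features$score[i], na.rm = TRUE)
      }
    }
    coverage[b] <- mean(covered)
  }
  data.frame(bin_start = starts, bin_stop = stops, count = count,
             coverage_fraction = coverage, max_score = max_score)
}

# per-base bitmap model of a cache entry's held set
bitmap_new <- function(n) logical(n)
bitmap_insert <- function(bm, start, stop) { bm[start:stop] <- TRUE; bm }
bitmap_plan <- function(bm, start, stop) {
  held <- bm[start:stop]
  list(covered_bases = (start:stop)[held], missing_bases = (start:stop)[!held])
}
iset_bases <- function(is) {
  if (nrow(is) == 0) return(numeric())
  unlist(lapply(seq_len(nrow(is)), function(i) is[i, "start"]:is[i, "stop"]))
}

# independent greedy first-fit row assignment in pixel space
oracle_first_fit <- function(features, vp, min_gap_px) {
  ord <- order(features$start, features$stop, features$feature_id)
  rows <- stats::setNames(rep(NA_integer_, nrow(features)),
                          features$feature_id)
  span <- vp$stop - vp$start + 1
  last <- numeric(0)
  for (i in ord) {
    s <- max(features$start[i], vp$start); e <- min(features$stop[i], vp$stop)
    if (s > e) next
    x1 <- max(0, floor((s - vp$start) * vp$pixel_width / span))
    x2 <- min(vp$pixel_width - 1,
              max(x1, ceiling((e - vp$start + 1) * vp$pixel_width / span) - 1))
    r <- 1
    while (r <= length(last) && x1 - last[r] - 1 < min_gap_px) r <- r + 1
    rows[i] <- r - 1L
    last[r] <- if (r > length(last)) x2 else max(last[r], x2)
  }
  rows
}

# feature tables sorted into a canonical order for equality comparison
canon_features <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$feature_id), ]
  rownames(df) <- NULL
  attr(df, "rejected") <- NULL
  df
}

expect_features_equal <- function(a, b) {
  expect_equal(canon_features(a), canon_features(b), ignore_attr = TRUE)
}

random_valid_session <- function(seed) {
  set.seed(seed)
  src <- das_source_ref(sprintf("http://host%d/das/src", sample(1:9, 1)),
                        title = "src",
                        capabilities = c("features", "sequence"))
  n_indep <- sample(1:3, 1)
  viewers <- lapply(seq_len(n_indep), function(i) {
    start <- sample(1:1e6, 1)
    span <- sample(c(100, 1e4, 1e6), 1)
    viewer_state(
      viewport(sample(c("chr1", "chr2", "chrX"), 1), start,
               start + span - 1, sample(c(500, 800, 1200), 1)),
      tracks = list(session_track(src$base_url, sprintf("t%d", i),
                                  track_style(glyph = sample(GLYPHS_FOR_TESTS, 1),
                                              min_gap_px = sample(0:5, 1)))))
  })
  # one linked trio: anchor + context zoom + next region
  # (start far enough in that the 10x context window never hits base 1,
  # which would shift its center)
  start <- sample(50001:1e6, 1); span <- 10000
  anchor <- viewer_state(viewport("chr1", start, start + span - 1, 1000),
                         link_group = "g1", link_role = "same_region_other_zoom")
  center <- (2 * start + span - 1) / 2
  wide_span <- span * 10
  wide_start <- max(1, center - (wide_span - 1) / 2)
  wide <- viewer_state(viewport("chr1", wide_start,
                                wide_start + wide_span - 1, 1000),
                       link_group = "g1", link_role = "same_region_other_zoom")
  nxt <- viewer_state(viewport("chr1", start + span, start + 2 * span - 1, 1000),
                      link_group = "g2", link_role = "adjacent_next")
  prev_anchor <- viewer_state(viewport("chr1", start, start + span - 1, 1000),
                              link_group = "g2", link_role = "independent")
  session_state(viewers = c(viewers, list(anchor, wide, nxt, prev_anchor)),
                registered_sources = list(src))
}

GLYPHS_FOR_TESTS <- c("box", "line", "arrow", "tick")
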