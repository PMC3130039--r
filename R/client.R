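# High-level client. Owns a transport, a cache and a configuration; answers
# "give me this window of this source at the right granularity" by planning
# against the cache, fetching only the missing sub-ranges, reducing to the
# tier, and storing at that resolution. Rendering a region is then: choose
# tier, assemble payloads, compose tracks, write the image.

#' Create a DAS client
#'
#' @param transport Transport function (see [http_transport()],
#'   [mock_transport()], [canned_transport()]).
#' @param config An `app_config` from [default_config()] / [read_config()].
#' @param verbose Log tier decisions and cache traffic to stderr.
#' @return A `das_client` environment.
#' @export
das_client <- function(transport = http_transport(), config = default_config(),
                       verbose = FALSE) {
  env <- new.env(parent = emptyenv())
  env$transport <- transport
  env$config <- config
  env$cache <- das_cache(budget_bytes = config$cache_budget_bytes,
                         ttl_seconds = Inf)
  env$verbose <- isTRUE(verbose)
  class(env) <- "das_client"
  env
}

#' @export
print.das_client <- function(x, ...) {
  cat("<das_client>\n")
  print(x$cache)
  invisible(x)
}

client_log <- function(client, fmt, ...) {
  if (client$verbose) message(sprintf(paste0("[dastrack] ", fmt), ...))
}

# Snap a window outward to the bin grid (anchored at base 1) so summary
# payloads cached for different requests tile exactly.
snap_to_bins <- function(start, stop, bin_width) {
  c(floor((start - 1) / bin_width) * bin_width + 1,
    ceiling(stop / bin_width) * bin_width)
}

#' Fetch the payload for a window at a tier, through the cache
#'
#' Plans the request against the cache, fetches only the missing sub-ranges
#' from the source, reduces each fetched piece to the tier's granularity,
#' caches it at that resolution, and assembles the full window. A base
#' fetched once under a (source, segment, tier) key is never fetched again.
#'
#' @param client A [das_client()].
#' @param source A [das_source_ref()].
#' @param segment_id Segment name.
#' @param start,stop Window, 1-based inclusive.
#' @param tier A [zoom_tier()].
#' @param kind `"features"` (default) or `"sequence"` (residues; only
#'   meaningful at the sequence tier).
#' @return The assembled payload: [das_features()], `summary_bins`, or a
#'   residues string.
#' @export
client_fetch <- function(client, source, segment_id, start, stop, tier,
                         kind = c("features", "sequence")) {
  kind <- match.arg(kind)
  # residues and base-level features are distinct payloads: separate tiers
  tlabel <- if (kind == "sequence") "residues" else tier_label(tier)
  key <- cache_key(source$base_url, segment_id, tlabel)
  want <- c(start, stop)
  if (kind == "features" && tier$kind == "summary")
    want <- snap_to_bins(start, stop, tier$bin_width)
  plan <- plan_fetch(client$cache, key, want[1], want[2])
  client_log(client, "%s %s:%s-%s [%s]: %d range(s) cached, %d missing",
             source$base_url, segment_id, format(start), format(stop), tlabel,
             nrow(plan$covered), nrow(plan$missing))
  if (nrow(plan$missing)) {
    for (i in seq_len(nrow(plan$missing))) {
      ms <- unname(plan$missing[i, "start"])
      me <- unname(plan$missing[i, "stop"])
      if (kind == "sequence") {
        xml <- das_fetch(source, "sequence", segment_id, ms, me,
                         transport = client$transport)
        payload <- parse_sequence(xml)
      } else {
        xml <- das_fetch(source, "features", segment_id, ms, me,
                         transport = client$transport)
        parsed <- parse_features(xml)
        window <- genomic_segment(segment_id, ms, me)
        payload <- reduce_payload(parsed$features, tier, window)
      }
      cache_insert(client$cache, key, ms, me, payload)
      client$cache$stats$fetched_bases <-
        client$cache$stats$fetched_bases + (me - ms + 1)
      client_log(client, "fetched %s:%s-%s (%s bases)", segment_id,
                 format(ms), format(me), format(me - ms + 1))
    }
  }
  cache_assemble(client$cache, key, want[1], want[2])
}

#' Discover the sources behind a base URL
#'
#' @param client A [das_client()].
#' @param base_url DAS base URL (registration is "simply entering its URL").
#' @return List of [das_source_ref()].
#' @export
client_sources <- function(client, base_url) {
  src <- das_source_ref(base_url, capabilities = "sources")
  parse_sources(das_fetch(src, "sources", transport = client$transport))
}

#' List a source's entry points (segments and lengths)
#'
#' @param client A [das_client()].
#' @param source A [das_source_ref()].
#' @return Data frame of segments (see [parse_entry_points()]).
#' @export
client_entry_points <- function(client, source) {
  parse_entry_points(das_fetch(source, "entry_points",
                               transport = client$transport))
}

#' Fetch, reduce, and render a region to an image file
#'
#' The full pipeline for one track container: choose the tier for the
#' window, fetch the payloads through the cache (only missing ranges are
#' requested), split features into one track per type category (one kind of
#' data per track), optionally top it with a residue row at base-level zoom,
#' and compose ruler + tracks into an SVG or PNG.
#'
#' @param client A [das_client()].
#' @param source A [das_source_ref()] (or list of them, drawn side by side).
#' @param segment_id Segment name.
#' @param start,stop Window, 1-based inclusive.
#' @param pixel_width Image width in pixels.
#' @param path Output file; extension does not matter, `format` decides.
#' @param format `"svg"` or `"png"` (default from config).
#' @param style_overrides Named list: type category -> [track_style()],
#'   overriding the configured styles.
#' @return Info list: `tier`, `bytes_like` counters `fetched_bases` (bases
#'   fetched by this call), `n_tracks`, `height`, `path`. The image is
#'   written to `path`.
#' @export
client_render <- function(client, source, segment_id, start, stop,
                          pixel_width = NULL, path, format = NULL,
                          style_overrides = list()) {
  cfg <- client$config
  if (is.null(pixel_width)) pixel_width <- cfg$pixel_width
  if (is.null(format)) format <- cfg$output_format
  sources <- if (inherits(source, "das_source_ref")) list(source) else source
  vp <- viewport(segment_id, start, stop, pixel_width)
  tier <- choose_tier(vp, individual_threshold = cfg$individual_threshold)
  client_log(client, "tier for %s:%s-%s at %d px: %s", segment_id,
             format(start), format(stop), pixel_width, tier_label(tier))
  fetched_before <- client$cache$stats$fetched_bases

  tracks <- list()
  for (src in sources) {
    if (tier$kind == "sequence" && "sequence" %in% src$capabilities) {
      residues <- client_fetch(client, src, segment_id, start, stop, tier,
                               kind = "sequence")
      seq_style <- track_style(track_height = 16, bg_color = "#FFFFFF")
      tracks <- c(tracks, list(view_track("sequence", residues, tier,
                                          seq_style, segment_id)))
    }
    payload <- client_fetch(client, src, segment_id, start, stop, tier)
    if (tier$kind == "summary") {
      st <- style_override(cfg, NA_character_, style_overrides)
      st$glyph <- "histogram"
      tracks <- c(tracks, list(view_track(src$title, payload, tier, st,
                                          segment_id)))
    } else {
      cats <- unique(payload$type_category)
      if (!length(cats)) cats <- NA_character_
      for (cat in cats) {
        sel <- if (is.na(cat)) is.na(payload$type_category)
               else !is.na(payload$type_category) & payload$type_category == cat
        sub <- payload[sel, , drop = FALSE]
        rownames(sub) <- NULL
        class(sub) <- c("das_features", "data.frame")
        st <- style_override(cfg, cat, style_overrides)
        label <- if (is.na(cat)) src$title else sprintf("%s (%s)", src$title, cat)
        tracks <- c(tracks, list(view_track(label, sub, tier, st, segment_id)))
      }
    }
  }
  img <- compose_view(vp, tracks, path = path, format = format,
                      ruler_height = cfg$ruler_height)
  fetched <- client$cache$stats$fetched_bases - fetched_before
  client_log(client, "rendered %d track(s) to %s (%s bases fetched)",
             length(tracks), path, format(fetched))
  height <- cfg$ruler_height +
    sum(vapply(tracks, function(t) t$style$track_height, numeric(1)))
  list(tier = tier, fetched_bases = fetched, n_tracks = length(tracks),
       height = height, path = path)
}

style_override <- function(cfg, category, overrides) {
  if (!is.na(category) && !is.null(overrides[[category]]))
    return(overrides[[category]])
  style_for_category(cfg, category)
}
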