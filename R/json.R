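# Compact JSON interchange for payloads. DAS XML is expressive but verbose;
# the JSON form is what a rendering client stores and moves around. The
# envelope is versioned and names the segment, the tier and the payload kind,
# with canonical key order so serialization is byte-deterministic.

PAYLOAD_FORMAT <- "dastrack-payload"
PAYLOAD_FORMAT_VERSION <- "1.0"

FEATURE_JSON_COLS <- c("feature_id", "label", "type_id", "type_category",
                       "method", "start", "stop", "score", "orientation",
                       "phase", "group_id", "link", "notes")
BIN_JSON_COLS <- c("bin_start", "bin_stop", "count", "coverage_fraction",
                   "max_score")

scalar_or_null <- function(x) {
  if (length(x) != 1 || is.na(x)) NULL else jsonlite::unbox(x)
}

features_to_list <- function(features) {
  f <- as.list(features)   # plain column vectors: fast row access
  lapply(seq_along(f$feature_id), function(i) {
    out <- list(
      feature_id = jsonlite::unbox(f$feature_id[i]),
      label = scalar_or_null(f$label[i]),
      type_id = jsonlite::unbox(f$type_id[i]),
      type_category = scalar_or_null(f$type_category[i]),
      method = scalar_or_null(f$method[i]),
      start = jsonlite::unbox(f$start[i]),
      stop = jsonlite::unbox(f$stop[i]),
      score = scalar_or_null(f$score[i]),
      orientation = jsonlite::unbox(f$orientation[i]),
      phase = scalar_or_null(f$phase[i]),
      group_id = scalar_or_null(f$group_id[i]),
      link = scalar_or_null(f$link[i]),
      notes = as.character(f$notes[[i]])
    )
    out[!vapply(out, is.null, logical(1))]
  })
}

bins_to_list <- function(bins) {
  b <- as.list(bins)
  lapply(seq_along(b$bin_start), function(i) {
    out <- list(
      bin_start = jsonlite::unbox(b$bin_start[i]),
      bin_stop = jsonlite::unbox(b$bin_stop[i]),
      count = jsonlite::unbox(b$count[i]),
      coverage_fraction = jsonlite::unbox(b$coverage_fraction[i]),
      max_score = scalar_or_null(b$max_score[i])
    )
    out[!vapply(out, is.null, logical(1))]
  })
}

serialize_payload <- function(payload) {
  body <- if (inherits(payload, "summary_bins")) bins_to_list(payload)
          else features_to_list(payload)
  as.character(jsonlite::toJSON(body, digits = NA, null = "null"))
}

#' Serialize a payload to the versioned JSON interchange format
#'
#' The payload kind must match the tier kind: feature tables go with
#' sequence/individual tiers, summary bins with summary tiers. For a fixed
#' dense feature set the summary-tier serialization is smaller in bytes than
#' the individual-tier one — data is stored at the required resolution, not
#' finer.
#'
#' @param segment The [genomic_segment()] window the payload covers.
#' @param payload A [das_features()] table or `summary_bins` data.frame.
#' @param tier The [zoom_tier()] the payload is reduced to.
#' @return JSON text (single string).
#' @export
features_to_json <- function(segment, payload, tier) {
  stopifnot(inherits(segment, "genomic_segment"), inherits(tier, "zoom_tier"))
  is_bins <- inherits(payload, "summary_bins")
  if (is_bins != (tier$kind == "summary"))
    stop_argument(sprintf("payload kind (%s) does not match tier kind '%s'",
                          if (is_bins) "bins" else "features", tier$kind))
  doc <- list(
    format = jsonlite::unbox(PAYLOAD_FORMAT),
    format_version = jsonlite::unbox(PAYLOAD_FORMAT_VERSION),
    segment = list(
      segment_id = jsonlite::unbox(segment$segment_id),
      start = jsonlite::unbox(segment$start),
      stop = jsonlite::unbox(segment$stop)
    ),
    tier = c(list(
      kind = jsonlite::unbox(tier$kind),
      bases_per_pixel = jsonlite::unbox(tier$bases_per_pixel)),
      if (tier$kind == "summary")
        list(bin_width = jsonlite::unbox(tier$bin_width))
    ),
    payload_kind = jsonlite::unbox(if (is_bins) "bins" else "features"),
    payload = if (is_bins) bins_to_list(payload) else features_to_list(payload)
  )
  as.character(jsonlite::toJSON(doc, digits = NA, null = "null"))
}

#' Parse the JSON interchange format back into the model
#'
#' Inverse of [features_to_json()]: parsing then re-serializing is
#' byte-identical, and the parsed payload equals the original model object.
#' Unknown format versions are rejected.
#'
#' @param json_text JSON produced by [features_to_json()].
#' @return A list with `segment`, `tier` and `payload`.
#' @export
payload_from_json <- function(json_text) {
  force(json_text)
  doc <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e) stop_parse(conditionMessage(e)))
  if (!identical(doc$format, PAYLOAD_FORMAT))
    stop_schema("not a payload document")
  if (!identical(doc$format_version, PAYLOAD_FORMAT_VERSION))
    stop_version(sprintf("unknown payload format version '%s'",
                         doc$format_version))
  segment <- genomic_segment(doc$segment$segment_id, doc$segment$start,
                             doc$segment$stop)
  tier <- zoom_tier(doc$tier$bases_per_pixel, doc$tier$kind,
                    bin_width = if (!is.null(doc$tier$bin_width))
                      doc$tier$bin_width else NA_real_)
  field <- function(rec, name, default) {
    v <- rec[[name]]
    if (is.null(v)) default else v
  }
  if (doc$payload_kind == "bins") {
    payload <- data.frame(
      bin_start = vapply(doc$payload, field, numeric(1), name = "bin_start", default = NA_real_),
      bin_stop = vapply(doc$payload, field, numeric(1), name = "bin_stop", default = NA_real_),
      count = vapply(doc$payload, function(r) as.integer(r$count), integer(1)),
      coverage_fraction = vapply(doc$payload, field, numeric(1),
                                 name = "coverage_fraction", default = NA_real_),
      max_score = vapply(doc$payload, function(r)
        as.numeric(field(r, "max_score", NA_real_)), numeric(1))
    )
    class(payload) <- c("summary_bins", "data.frame")
  } else if (doc$payload_kind == "features") {
    recs <- doc$payload
    payload <- das_features(
      feature_id = vapply(recs, field, character(1), name = "feature_id", default = NA_character_),
      label = vapply(recs, function(r) as.character(field(r, "label", NA_character_)), character(1)),
      type_id = vapply(recs, field, character(1), name = "type_id", default = NA_character_),
      type_category = vapply(recs, function(r)
        as.character(field(r, "type_category", NA_character_)), character(1)),
      method = vapply(recs, function(r)
        as.character(field(r, "method", NA_character_)), character(1)),
      start = vapply(recs, field, numeric(1), name = "start", default = NA_real_),
      stop = vapply(recs, field, numeric(1), name = "stop", default = NA_real_),
      score = vapply(recs, function(r)
        as.numeric(field(r, "score", NA_real_)), numeric(1)),
      orientation = vapply(recs, field, character(1), name = "orientation",
                           default = "unstranded"),
      phase = vapply(recs, function(r)
        as.integer(field(r, "phase", NA_integer_)), integer(1)),
      group_id = vapply(recs, function(r)
        as.character(field(r, "group_id", NA_character_)), character(1)),
      link = vapply(recs, function(r)
        as.character(field(r, "link", NA_character_)), character(1)),
      notes = lapply(recs, function(r) as.character(unlist(r$notes)))
    )
  } else {
    stop_schema(sprintf("unknown payload kind '%s'", doc$payload_kind))
  }
  list(segment = segment, tier = tier, payload = payload)
}

#' Write features as GFF3
#'
#' One GFF3 line per feature; 1-based inclusive coordinates are preserved
#' as-is (GFF3 uses the same convention), orientation maps to `+`/`-`/`.`.
#'
#' @param features A [das_features()] table.
#' @param segment The [genomic_segment()] the features live on (provides the
#'   seqid and the `##sequence-region` pragma).
#' @param source_label Text for GFF column 2.
#' @return GFF3 text (single string, trailing newline).
#' @export
export_gff3 <- function(features, segment, source_label = "dastrack") {
  stopifnot(inherits(segment, "genomic_segment"))
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s %s %s", segment$segment_id,
                      format(segment$start, scientific = FALSE),
                      format(segment$stop, scientific = FALSE)))
  if (nrow(features) == 0)
    return(paste0(paste(header, collapse = "\n"), "\n"))
  gff_escape <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x
  }
  strand <- c(forward = "+", reverse = "-", unstranded = ".")[features$orientation]
  attrs <- vapply(seq_len(nrow(features)), function(i) {
    parts <- c(sprintf("ID=%s", gff_escape(features$feature_id[i])))
    if (!is.na(features$label[i]))
      parts <- c(parts, sprintf("Name=%s", gff_escape(features$label[i])))
    if (!is.na(features$group_id[i]))
      parts <- c(parts, sprintf("das_group=%s", gff_escape(features$group_id[i])))
    notes <- features$notes[[i]]
    if (length(notes))
      parts <- c(parts, sprintf("Note=%s",
                                paste(gff_escape(notes), collapse = ",")))
    paste(parts, collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   segment$segment_id,
                   ifelse(is.na(features$method), source_label, features$method),
                   features$type_id,
                   format(features$start, scientific = FALSE, trim = TRUE),
                   format(features$stop, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(features$score), ".",
                          formatC(features$score, format = "g", digits = 6)),
                   unname(strand),
                   ifelse(is.na(features$phase), ".", as.character(features$phase)),
                   attrs)
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}
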