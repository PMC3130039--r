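# The DAS data model. Coordinates are 1-based inclusive everywhere in the
# public interface (the DAS convention); any half-open arithmetic is internal.

DAS_COMMANDS <- c("sources", "entry_points", "sequence", "features",
                  "types", "stylesheet")
ORIENTATIONS <- c("forward", "reverse", "unstranded")

#' Reference to a DAS source
#'
#' A DAS source is one annotation server endpoint, addressed by its base URL.
#' The URL is normalized by stripping any trailing slash so request
#' construction is uniform.
#'
#' @param base_url Base URL of the source (e.g. `"http://host/das/hg19"`).
#' @param title Human-readable title.
#' @param capabilities Character vector of DAS command names the source
#'   supports; subset of `sources`, `entry_points`, `sequence`, `features`,
#'   `types`, `stylesheet`.
#' @param coordinate_system Free-text assembly label (e.g. `"GRCh37"`).
#' @return An object of class `das_source_ref`.
#' @export
das_source_ref <- function(base_url, title = base_url,
                           capabilities = c("features", "sequence", "entry_points"),
                           coordinate_system = NA_character_) {
  if (!is.character(base_url) || length(base_url) != 1L || !nzchar(base_url))
    stop_argument("base_url must be a non-empty string")
  base_url <- sub("/+$", "", base_url)
  capabilities <- unique(as.character(capabilities))
  bad <- setdiff(capabilities, DAS_COMMANDS)
  if (length(bad))
    stop_argument(sprintf("unknown DAS capabilities: %s", paste(bad, collapse = ", ")))
  structure(
    list(base_url = base_url, title = as.character(title)[1],
         capabilities = capabilities,
         coordinate_system = as.character(coordinate_system)[1]),
    class = "das_source_ref"
  )
}

#' @export
print.das_source_ref <- function(x, ...) {
  cat("<das_source_ref> ", x$base_url, "\n", sep = "")
  cat("  title:        ", x$title, "\n", sep = "")
  cat("  coordinates:  ", x$coordinate_system, "\n", sep = "")
  cat("  capabilities: ", paste(x$capabilities, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' A named reference segment window
#'
#' A segment is a named reference sequence (typically a chromosome); a
#' `genomic_segment` addresses a 1-based inclusive window on it.
#'
#' @param segment_id Segment name (e.g. `"chr1"`).
#' @param start,stop 1-based inclusive bounds, `start <= stop`.
#' @param version Optional segment version string.
#' @param total_length Optional full length of the segment in bp.
#' @return An object of class `genomic_segment`.
#' @export
genomic_segment <- function(segment_id, start, stop, version = NA_character_,
                            total_length = NA_real_) {
  if (!nzchar(segment_id)) stop_argument("segment_id must be non-empty")
  start <- as.numeric(start); stop <- as.numeric(stop)
  if (is.na(start) || is.na(stop) || start < 1 || start > stop)
    stop_argument(sprintf("invalid segment range [%s, %s]: need 1 <= start <= stop",
                          format(start), format(stop)))
  total_length <- as.numeric(total_length)[1]
  if (!is.na(total_length) && stop > total_length)
    stop_argument(sprintf("segment %s: stop %s exceeds total length %s",
                          segment_id, format(stop), format(total_length)))
  structure(
    list(segment_id = as.character(segment_id)[1], start = start, stop = stop,
         version = as.character(version)[1], total_length = total_length),
    class = "genomic_segment"
  )
}

#' @export
print.genomic_segment <- function(x, ...) {
  cat(sprintf("<genomic_segment> %s:%s-%s (%s bp)\n", x$segment_id,
              format(x$start, big.mark = ","), format(x$stop, big.mark = ","),
              format(segment_span(x), big.mark = ",")))
  invisible(x)
}

segment_span <- function(segment) segment$stop - segment$start + 1

#' Construct a table of DAS features
#'
#' Features are annotated intervals on a segment: each has a type, optional
#' method, score, orientation, phase, group and notes. They are held in a
#' classed `data.frame` with one row per feature; `notes` is a list-column of
#' character vectors.
#'
#' @param feature_id Character vector of unique feature identifiers.
#' @param start,stop 1-based inclusive coordinates (numeric).
#' @param type_id Feature type identifiers.
#' @param label Optional display labels (`NA` for none).
#' @param type_category,method Optional annotation fields.
#' @param score Optional numeric scores (`NA` for none; must be finite when
#'   present).
#' @param orientation One of `"forward"`, `"reverse"`, `"unstranded"`.
#' @param phase Optional reading-frame phase: 0, 1, 2 or `NA`.
#' @param group_id Optional group identifier (features of one gene-like group
#'   share it).
#' @param link Optional URL per feature.
#' @param notes List of character vectors (one per feature), or `NULL`.
#' @return A `das_features` data.frame.
#' @export
das_features <- function(feature_id = character(), start = numeric(),
                         stop = numeric(), type_id = character(),
                         label = NA_character_, type_category = NA_character_,
                         method = NA_character_, score = NA_real_,
                         orientation = "unstranded", phase = NA_integer_,
                         group_id = NA_character_, link = NA_character_,
                         notes = NULL) {
  n <- length(feature_id)
  df <- data.frame(
    feature_id = as.character(feature_id),
    label = rep_len(as.character(label), n),
    type_id = if (n) rep_len(as.character(type_id), n) else character(),
    type_category = rep_len(as.character(type_category), n),
    method = rep_len(as.character(method), n),
    start = rep_len(as.numeric(start), n),
    stop = rep_len(as.numeric(stop), n),
    score = rep_len(as.numeric(score), n),
    orientation = rep_len(as.character(orientation), n),
    phase = rep_len(as.integer(phase), n),
    group_id = rep_len(as.character(group_id), n),
    link = rep_len(as.character(link), n),
    stringsAsFactors = FALSE
  )
  if (n == 0) df <- df[0, ]
  if (is.null(notes)) notes <- rep(list(character()), n)
  df$notes <- notes
  class(df) <- c("das_features", "data.frame")
  validate_features(df)
}

validate_features <- function(df, collect = FALSE) {
  bad_range <- !is.na(df$start) & !is.na(df$stop) &
    (df$start < 1 | df$stop < df$start)
  bad_score <- !is.na(df$score) & !is.finite(df$score)
  bad_orient <- !(df$orientation %in% ORIENTATIONS)
  bad_phase <- !is.na(df$phase) & !(df$phase %in% 0:2)
  bad <- bad_range | bad_score | bad_orient | bad_phase
  if (any(bad)) {
    msg <- sprintf("invalid feature record(s): %s",
                   paste(df$feature_id[bad], collapse = ", "))
    if (collect) return(list(features = df[!bad, ], rejected = df$feature_id[bad],
                             message = msg))
    stop_validation(msg, rejected = df$feature_id[bad])
  }
  if (collect) list(features = df, rejected = character(), message = NULL) else df
}

#' @export
print.das_features <- function(x, ...) {
  cat(sprintf("<das_features> %d feature(s)\n", nrow(x)))
  if (nrow(x)) {
    shown <- utils::head(as.data.frame(x)[c("feature_id", "type_id", "start",
                                            "stop", "score", "orientation")], 10)
    print(shown)
    if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

empty_features <- function() das_features()

#' A block of reference sequence residues
#'
#' @param segment A [genomic_segment()] giving the window the residues cover.
#' @param residues A single string over `A,C,G,T,N` (either case), of length
#'   exactly `stop - start + 1`.
#' @return An object of class `sequence_block`.
#' @export
sequence_block <- function(segment, residues) {
  stopifnot(inherits(segment, "genomic_segment"))
  residues <- as.character(residues)[1]
  if (nchar(residues) != segment_span(segment))
    stop_validation(sprintf(
      "sequence length %d does not match declared span %s:%s-%s (%d bp)",
      nchar(residues), segment$segment_id, format(segment$start),
      format(segment$stop), segment_span(segment)))
  if (grepl("[^ACGTNacgtn]", residues))
    stop_validation("residues contain characters outside {A,C,G,T,N}")
  structure(list(segment = segment, residues = residues),
            class = "sequence_block")
}

#' @export
print.sequence_block <- function(x, ...) {
  cat(sprintf("<sequence_block> %s:%s-%s\n", x$segment$segment_id,
              format(x$segment$start), format(x$segment$stop)))
  r <- x$residues
  cat("  ", if (nchar(r) > 60) paste0(substr(r, 1, 60), "...") else r, "\n", sep = "")
  invisible(x)
}

# orientation <-> DAS/GFF strand symbol
orientation_to_symbol <- function(o) {
  unname(c(forward = "+", reverse = "-", unstranded = "0")[o])
}
symbol_to_orientation <- function(s) {
  out <- rep("unstranded", length(s))
  out[s %in% "+"] <- "forward"
  out[s %in% "-"] <- "reverse"
  out
}
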