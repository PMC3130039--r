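# Session persistence. The full application state — every viewer with its
# viewport, tracks and styles, the link groups tying viewers together, and
# the registered sources — is saved to a flat text file (pretty-printed JSON
# with a format version and canonical key order: shareable, diffable, and
# rejected cleanly by readers that do not know the version). Sessions store
# source URLs, not data: rebuilding a session re-fetches.

SESSION_FORMAT <- "dastrack-session"
SESSION_FORMAT_VERSION <- "1.0"
LINK_ROLES <- c("independent", "same_region_other_zoom", "adjacent_next",
                "adjacent_previous")

#' Declare a track of a saved viewer
#'
#' @param source_url DAS source base URL the track draws from.
#' @param label Track label.
#' @param style A [track_style()].
#' @return A `session_track` list.
#' @export
session_track <- function(source_url, label, style = track_style()) {
  if (!nzchar(source_url)) stop_argument("source_url must be non-empty")
  structure(list(source_url = source_url, label = as.character(label),
                 style = style), class = "session_track")
}

#' State of one viewer (track container)
#'
#' @param viewport A [viewport()].
#' @param tracks List of [session_track()]s, in drawing order.
#' @param link_group Optional group name tying synchronized viewers
#'   together; required when `link_role` is not `"independent"`.
#' @param link_role How this viewer relates to its link group:
#'   `"independent"`, `"same_region_other_zoom"` (same segment and center,
#'   another zoom), `"adjacent_next"` / `"adjacent_previous"` (abutting
#'   windows extending the region).
#' @return A `viewer_state` list.
#' @export
viewer_state <- function(viewport, tracks = list(),
                         link_group = NA_character_,
                         link_role = "independent") {
  stopifnot(inherits(viewport, "viewport"))
  link_role <- match.arg(link_role, LINK_ROLES)
  if (link_role != "independent" && is.na(link_group))
    stop_validation(sprintf("link_role '%s' requires a link_group", link_role))
  structure(list(viewport = viewport, tracks = tracks,
                 link_group = as.character(link_group), link_role = link_role),
            class = "viewer_state")
}

#' Full application state
#'
#' @param viewers List of [viewer_state()]s.
#' @param registered_sources List of [das_source_ref()]s.
#' @return A `session_state`; link-group invariants are checked.
#' @export
session_state <- function(viewers = list(), registered_sources = list()) {
  state <- structure(list(format_version = SESSION_FORMAT_VERSION,
                          viewers = viewers,
                          registered_sources = registered_sources),
                     class = "session_state")
  validate_session(state)
  state
}

viewer_center <- function(v) (v$viewport$start + v$viewport$stop) / 2

validate_session <- function(state) {
  viewers <- state$viewers
  groups <- unique(stats::na.omit(vapply(viewers, `[[`, character(1),
                                         "link_group")))
  for (g in groups) {
    members <- Filter(function(v) identical(v$link_group, g), viewers)
    # same-region members of a group (and any independent anchor in it)
    # must share segment and center
    sr <- Filter(function(v) v$link_role == "same_region_other_zoom", members)
    if (length(sr)) {
      pool <- c(sr, Filter(function(v) v$link_role == "independent", members))
      segs <- unique(vapply(pool, function(v) v$viewport$segment_id,
                            character(1)))
      if (length(segs) > 1)
        stop_validation(sprintf(
          "link group '%s': same-region viewers span different segments", g))
      centers <- unique(vapply(pool, viewer_center, numeric(1)))
      if (length(centers) > 1)
        stop_validation(sprintf(
          "link group '%s': same-region viewers do not share a center", g))
    }
    # adjacent members must abut some other member of the group
    for (v in members) {
      if (v$link_role == "adjacent_next") {
        ok <- any(vapply(members, function(w)
          !identical(w, v) && w$viewport$stop + 1 == v$viewport$start,
          logical(1)))
        if (!ok) stop_validation(sprintf(
          "link group '%s': adjacent_next viewer at %s:%s does not abut a previous viewer",
          g, v$viewport$segment_id, format(v$viewport$start)))
      }
      if (v$link_role == "adjacent_previous") {
        ok <- any(vapply(members, function(w)
          !identical(w, v) && v$viewport$stop + 1 == w$viewport$start,
          logical(1)))
        if (!ok) stop_validation(sprintf(
          "link group '%s': adjacent_previous viewer at %s:%s does not abut a next viewer",
          g, v$viewport$segment_id, format(v$viewport$start)))
      }
    }
  }
  invisible(state)
}

style_to_list <- function(style) {
  list(glyph = jsonlite::unbox(style$glyph),
       fg_color = jsonlite::unbox(style$fg_color),
       bg_color = jsonlite::unbox(style$bg_color),
       track_height = jsonlite::unbox(style$track_height),
       row_height = jsonlite::unbox(style$row_height),
       min_gap_px = jsonlite::unbox(style$min_gap_px),
       show_labels = jsonlite::unbox(style$show_labels))
}

#' Serialize a session to flat text
#'
#' Canonical key order and pretty printing: saving the same state twice
#' yields identical bytes. Invariants are re-checked before writing.
#'
#' @param state A [session_state()].
#' @param path Optional file to write to.
#' @return The session text (invisibly when written to `path`).
#' @export
save_session <- function(state, path = NULL) {
  stopifnot(inherits(state, "session_state"))
  validate_session(state)
  doc <- list(
    format = jsonlite::unbox(SESSION_FORMAT),
    format_version = jsonlite::unbox(state$format_version),
    viewers = lapply(state$viewers, function(v) list(
      viewport = list(segment_id = jsonlite::unbox(v$viewport$segment_id),
                      start = jsonlite::unbox(v$viewport$start),
                      stop = jsonlite::unbox(v$viewport$stop),
                      pixel_width = jsonlite::unbox(v$viewport$pixel_width)),
      tracks = lapply(v$tracks, function(tr) list(
        source_url = jsonlite::unbox(tr$source_url),
        label = jsonlite::unbox(tr$label),
        style = style_to_list(tr$style))),
      link_group = if (is.na(v$link_group)) NULL
                   else jsonlite::unbox(v$link_group),
      link_role = jsonlite::unbox(v$link_role))),
    registered_sources = lapply(state$registered_sources, function(s) list(
      base_url = jsonlite::unbox(s$base_url),
      title = jsonlite::unbox(s$title),
      capabilities = s$capabilities,
      coordinate_system = if (is.na(s$coordinate_system)) NULL
                          else jsonlite::unbox(s$coordinate_system)))
  )
  text <- as.character(jsonlite::toJSON(doc, pretty = 2, digits = NA,
                                        null = "null"))
  text <- paste0(text, "\n")
  if (!is.null(path)) {
    writeChar(text, path, eos = NULL)
    return(invisible(text))
  }
  text
}

#' Rebuild a session from its flat-text form
#'
#' Inverse of [save_session()]; unknown format versions are rejected and
#' all invariants are re-checked, so loading never yields a state that
#' violates them.
#'
#' @param text Session text, or `path` to read from.
#' @param path File to read (used when `text` is missing).
#' @return A [session_state()].
#' @export
load_session <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop_argument("need session text or a path")
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop_parse(sprintf("malformed session file: %s",
                                       conditionMessage(e))))
  if (!identical(doc$format, SESSION_FORMAT))
    stop_schema("not a session file")
  if (!identical(doc$format_version, SESSION_FORMAT_VERSION))
    stop_version(sprintf("unknown session format version '%s'",
                         doc$format_version))
  viewers <- lapply(doc$viewers, function(v) {
    vp <- viewport(v$viewport$segment_id, v$viewport$start, v$viewport$stop,
                   v$viewport$pixel_width)
    tracks <- lapply(v$tracks, function(tr) {
      st <- tr$style
      session_track(tr$source_url, tr$label,
                    track_style(glyph = st$glyph, fg_color = st$fg_color,
                                bg_color = st$bg_color,
                                track_height = st$track_height,
                                row_height = st$row_height,
                                min_gap_px = st$min_gap_px,
                                show_labels = st$show_labels))
    })
    viewer_state(vp, tracks,
                 link_group = if (is.null(v$link_group)) NA_character_
                              else v$link_group,
                 link_role = v$link_role)
  })
  sources <- lapply(doc$registered_sources, function(s)
    das_source_ref(s$base_url, title = s$title,
                   capabilities = unlist(s$capabilities),
                   coordinate_system = if (is.null(s$coordinate_system))
                     NA_character_ else s$coordinate_system))
  session_state(viewers = viewers, registered_sources = sources)
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("<session_state> v%s: %d viewer(s), %d source(s)\n",
              x$format_version, length(x$viewers),
              length(x$registered_sources)))
  for (v in x$viewers)
    cat(sprintf("  %s:%s-%s @ %s px [%s]%s\n", v$viewport$segment_id,
                format(v$viewport$start, big.mark = ","),
                format(v$viewport$stop, big.mark = ","),
                format(v$viewport$pixel_width), v$link_role,
                if (!is.na(v$link_group))
                  sprintf(" group=%s", v$link_group) else ""))
  invisible(x)
}
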