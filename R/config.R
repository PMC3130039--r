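# Track styles and application configuration. End users pick a glyph and
# colors per track; administrators ship per-category defaults in a YAML
# config file. CLI flags override config values, config overrides built-ins.

GLYPHS <- c("box", "line", "arrow", "tick", "histogram")

#' How to draw a track
#'
#' @param glyph Drawing tool: `"box"`, `"line"`, `"arrow"` (orientation
#'   encoded as the arrowhead direction), `"tick"` or `"histogram"`.
#' @param fg_color,bg_color Hex colors (`"#RRGGBB"`).
#' @param track_height Total track height in pixels.
#' @param row_height Height of one bump row in pixels.
#' @param min_gap_px Minimum horizontal clearance between same-row glyphs.
#' @param show_labels Draw feature labels when there is room (glyph at least
#'   30 px wide).
#' @return An object of class `track_style`.
#' @export
track_style <- function(glyph = "box", fg_color = "#3366CC",
                        bg_color = "#FFFFFF", track_height = 60,
                        row_height = 12, min_gap_px = 2, show_labels = FALSE) {
  glyph <- match.arg(glyph, GLYPHS)
  if (track_height < 1 || row_height < 1) stop_argument("heights must be >= 1")
  if (min_gap_px < 0) stop_argument("min_gap_px must be >= 0")
  structure(list(glyph = glyph, fg_color = toupper(fg_color),
                 bg_color = toupper(bg_color),
                 track_height = as.numeric(track_height),
                 row_height = as.numeric(row_height),
                 min_gap_px = as.numeric(min_gap_px),
                 show_labels = isTRUE(show_labels)),
            class = "track_style")
}

#' @export
print.track_style <- function(x, ...) {
  cat(sprintf("<track_style> %s, fg %s on %s, %gx%g px rows, gap %g px\n",
              x$glyph, x$fg_color, x$bg_color, x$track_height, x$row_height,
              x$min_gap_px))
  invisible(x)
}

#' Built-in application configuration defaults
#'
#' Tier thresholds and the bin-width ladder, cache budget and TTL, HTTP
#' timeout, per-category track style defaults, and the default output image
#' format. All values can be overridden from a YAML config file
#' ([read_config()]) and, for the CLI, by command-line flags.
#'
#' @return A list of class `app_config`.
#' @export
default_config <- function() {
  structure(list(
    individual_threshold = 1000,    # bp/px boundary individual -> summary
    sequence_threshold = 1 / 8,     # bp/px boundary sequence -> individual
    cache_budget_bytes = 256 * 1024^2,
    cache_ttl_seconds = 300,
    http_timeout_seconds = 30,
    output_format = "svg",
    ruler_height = 20,
    pixel_width = 1000,
    styles = list(
      default = track_style(),
      transcription = track_style(glyph = "arrow", fg_color = "#CC4422"),
      variation = track_style(glyph = "tick", fg_color = "#228833",
                              track_height = 30),
      repeat_region = track_style(glyph = "box", fg_color = "#888888",
                                  track_height = 30)
    )
  ), class = "app_config")
}

config_numeric_fields <- c("individual_threshold", "sequence_threshold",
                           "cache_budget_bytes", "cache_ttl_seconds",
                           "http_timeout_seconds", "ruler_height",
                           "pixel_width")

#' Read a YAML configuration file over the built-in defaults
#'
#' Unknown keys are ignored; numeric fields must be positive. Styles are
#' given as maps under `styles:` keyed by type category, each with any of
#' the [track_style()] fields.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An `app_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_argument(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  for (f in intersect(names(raw), config_numeric_fields)) {
    v <- as.numeric(raw[[f]])
    if (is.na(v) || v <= 0)
      stop_validation(sprintf("config field %s must be a positive number", f))
    cfg[[f]] <- v
  }
  if (!is.null(raw$output_format))
    cfg$output_format <- match.arg(raw$output_format, c("svg", "png"))
  for (cat in names(raw$styles)) {
    base <- if (!is.null(cfg$styles[[cat]])) cfg$styles[[cat]]
            else cfg$styles$default
    over <- raw$styles[[cat]]
    args <- utils::modifyList(unclass(base), over)
    cfg$styles[[cat]] <- do.call(track_style, args)
  }
  cfg
}

#' Pick the configured style for a feature type category
#'
#' @param config An `app_config`.
#' @param type_category Category string (or `NA`).
#' @return A [track_style()]; the `default` entry when the category has no
#'   specific style.
#' @export
style_for_category <- function(config, type_category) {
  if (!is.na(type_category) && !is.null(config$styles[[type_category]]))
    config$styles[[type_category]]
  else config$styles$default
}

#' Write the full default configuration to a YAML file
#'
#' Useful as a starting point for site-specific configuration.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  cfg <- default_config()
  out <- cfg[config_numeric_fields]
  out$output_format <- cfg$output_format
  out$styles <- lapply(cfg$styles, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}
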