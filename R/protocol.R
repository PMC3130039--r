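# DAS 1.53 request construction and response parsing.
#
# Request grammar: <base_url>/<command>[?segment=ID[:START,STOP]]
# Responses are XML; parsers map them onto the domain model and ignore
# unknown elements/attributes (real servers vary in dialect). Records that
# violate the coordinate invariant are rejected per record, not per document,
# so one bad record cannot blank a whole track.

#' Build a DAS request URL
#'
#' @param source A [das_source_ref()].
#' @param command DAS command name; must be among the source's capabilities.
#' @param segment_id Optional segment name.
#' @param start,stop Optional 1-based inclusive range; only allowed together
#'   with `segment_id`.
#' @return The request URL as a string.
#' @examples
#' src <- das_source_ref("http://example.org/das/hg19")
#' build_request(src, "features", "1", 100, 200)
#' @export
build_request <- function(source, command, segment_id = NULL,
                          start = NULL, stop = NULL) {
  stopifnot(inherits(source, "das_source_ref"))
  command <- as.character(command)[1]
  if (!command %in% DAS_COMMANDS)
    stop_argument(sprintf("unknown DAS command '%s'", command))
  if (!command %in% source$capabilities)
    stop_capability(sprintf("source %s does not support command '%s'",
                            source$base_url, command))
  has_range <- !is.null(start) || !is.null(stop)
  if (has_range && is.null(segment_id))
    stop_argument("a start/stop range requires a segment_id")
  if (has_range && (is.null(start) || is.null(stop)))
    stop_argument("start and stop must be given together")
  url <- paste0(source$base_url, "/", command)
  if (!is.null(segment_id)) {
    seg <- as.character(segment_id)[1]
    if (has_range) {
      start <- as.numeric(start); stop <- as.numeric(stop)
      if (start > stop) stop_argument("start must be <= stop")
      url <- sprintf("%s?segment=%s:%s,%s", url, seg,
                     format(start, scientific = FALSE),
                     format(stop, scientific = FALSE))
    } else {
      url <- sprintf("%s?segment=%s", url, seg)
    }
  }
  url
}

read_xml_checked <- function(xml_text) {
  force(xml_text)   # lazy arg must not be evaluated inside the tryCatch
  tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) {
      stop_parse(sprintf("malformed XML: %s", conditionMessage(e)))
    }
  )
}

xml_attr_or_na <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || !nzchar(v)) NA_character_ else v
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Parse a DAS features document
#'
#' Parses a DASGFF features response into the segment it covers and a
#' [das_features()] table, preserving document order. Unknown child elements
#' are ignored. Features with `stop < start` are rejected record-by-record and
#' reported in the `rejected` attribute (and as a warning); the rest of the
#' document still parses.
#'
#' @param xml_text DAS features XML, as a string or raw vector.
#' @return A list with elements `segment` ([genomic_segment()]) and
#'   `features` ([das_features()] with attribute `rejected` listing the ids of
#'   any invalid records).
#' @export
parse_features <- function(xml_text) {
  doc <- read_xml_checked(xml_text)
  seg_node <- xml2::xml_find_first(doc, ".//SEGMENT")
  if (inherits(seg_node, "xml_missing"))
    stop_schema("features document has no SEGMENT element")
  err_node <- xml2::xml_find_first(doc, ".//ERRORSEGMENT | .//UNKNOWNSEGMENT")
  if (!inherits(err_node, "xml_missing"))
    stop_schema(sprintf("server reported unknown/error segment '%s'",
                        xml_attr_or_na(err_node, "id")))
  segment <- genomic_segment(
    segment_id = xml2::xml_attr(seg_node, "id"),
    start = num_or_na(xml2::xml_attr(seg_node, "start")),
    stop = num_or_na(xml2::xml_attr(seg_node, "stop")),
    version = xml_attr_or_na(seg_node, "version")
  )
  fnodes <- xml2::xml_find_all(seg_node, "./FEATURE")
  n <- length(fnodes)
  if (n == 0)
    return(list(segment = segment, features = empty_features()))

  # one pass over each FEATURE's children (much cheaper than per-field xpath
  # on large documents); unknown child elements fall through untouched
  recs <- lapply(fnodes, function(f) {
    kids <- xml2::xml_children(f)
    nm <- xml2::xml_name(kids)
    node_of <- function(name) {
      i <- match(name, nm)
      if (is.na(i)) NULL else kids[[i]]
    }
    txt <- function(node) if (is.null(node)) NA_character_ else xml2::xml_text(node)
    att <- function(node, a) if (is.null(node)) NA_character_ else xml2::xml_attr(node, a)
    type <- node_of("TYPE")
    list(type_id = att(type, "id"), type_category = att(type, "category"),
         method = att(node_of("METHOD"), "id"),
         start = txt(node_of("START")), stop = txt(node_of("END")),
         score = txt(node_of("SCORE")),
         orientation = txt(node_of("ORIENTATION")),
         phase = txt(node_of("PHASE")),
         group_id = att(node_of("GROUP"), "id"),
         link = att(node_of("LINK"), "href"),
         notes = xml2::xml_text(kids[nm == "NOTE"]))
  })
  col <- function(name) vapply(recs, `[[`, character(1), name)
  score_txt <- col("score")
  phase_txt <- col("phase")
  orient_txt <- col("orientation")
  df <- data.frame(
    feature_id = xml2::xml_attr(fnodes, "id"),
    label = xml2::xml_attr(fnodes, "label"),
    type_id = col("type_id"),
    type_category = col("type_category"),
    method = col("method"),
    start = num_or_na(col("start")),
    stop = num_or_na(col("stop")),
    score = num_or_na(ifelse(score_txt %in% c("-", ""), NA, score_txt)),
    orientation = symbol_to_orientation(trimws(ifelse(is.na(orient_txt), "0",
                                                      orient_txt))),
    phase = suppressWarnings(as.integer(ifelse(phase_txt %in% c("-", ""),
                                               NA, phase_txt))),
    group_id = col("group_id"),
    link = col("link"),
    stringsAsFactors = FALSE
  )
  df$notes <- lapply(recs, `[[`, "notes")
  class(df) <- c("das_features", "data.frame")

  if (any(is.na(df$start) | is.na(df$stop)))
    stop_schema(sprintf(
      "feature(s) missing START/END: %s",
      paste(df$feature_id[is.na(df$start) | is.na(df$stop)], collapse = ", ")))
  checked <- validate_features(df, collect = TRUE)
  feats <- checked$features
  rownames(feats) <- NULL
  if (length(checked$rejected)) {
    warning(checked$message, call. = FALSE)
    attr(feats, "rejected") <- checked$rejected
  }
  list(segment = segment, features = feats)
}

#' Parse a DAS sources (or legacy DSN) document
#'
#' Accepts both the `SOURCES` document (with `CAPABILITY` and `COORDINATES`
#' elements) and the legacy `DASDSN` listing. For DSN entries, which carry no
#' capability information, capabilities default to
#' `features`, `sequence`, `entry_points`.
#'
#' @param xml_text Sources XML.
#' @return A list of [das_source_ref()] objects.
#' @export
parse_sources <- function(xml_text) {
  doc <- read_xml_checked(xml_text)
  root <- xml2::xml_name(doc)
  if (root == "SOURCES") {
    nodes <- xml2::xml_find_all(doc, ".//SOURCE")
    return(lapply(nodes, function(s) {
      ver <- xml2::xml_find_first(s, "./VERSION")
      caps <- xml2::xml_attr(xml2::xml_find_all(s, ".//CAPABILITY"), "type")
      caps <- sub("^das1?:", "", caps)
      caps <- intersect(caps, DAS_COMMANDS)
      coord <- xml2::xml_find_first(s, ".//COORDINATES")
      uri <- xml_attr_or_na(if (!inherits(ver, "xml_missing")) ver else s, "uri")
      das_source_ref(
        base_url = uri,
        title = if (!is.na(xml_attr_or_na(s, "title")))
          xml2::xml_attr(s, "title") else uri,
        capabilities = if (length(caps)) caps else "features",
        coordinate_system = if (inherits(coord, "xml_missing")) NA_character_
          else xml2::xml_text(coord)
      )
    }))
  }
  if (root == "DASDSN") {
    nodes <- xml2::xml_find_all(doc, ".//DSN")
    return(lapply(nodes, function(d) {
      src <- xml2::xml_find_first(d, "./SOURCE")
      mm <- xml2::xml_find_first(d, "./MAPMASTER")
      das_source_ref(
        base_url = if (!inherits(mm, "xml_missing")) xml2::xml_text(mm)
          else xml2::xml_attr(src, "id"),
        title = if (!inherits(src, "xml_missing")) xml2::xml_text(src)
          else NA_character_
      )
    }))
  }
  stop_schema(sprintf("unrecognized sources document root <%s>", root))
}

#' Parse a DAS entry_points document
#'
#' @param xml_text Entry points XML.
#' @return A data.frame with columns `segment_id`, `start`, `stop`,
#'   `total_length`.
#' @export
parse_entry_points <- function(xml_text) {
  doc <- read_xml_checked(xml_text)
  nodes <- xml2::xml_find_all(doc, ".//SEGMENT")
  data.frame(
    segment_id = xml2::xml_attr(nodes, "id"),
    start = num_or_na(xml2::xml_attr(nodes, "start")),
    stop = num_or_na(xml2::xml_attr(nodes, "stop")),
    total_length = num_or_na(xml2::xml_attr(nodes, "stop")),
    stringsAsFactors = FALSE
  )
}

#' Parse a DAS sequence document
#'
#' @param xml_text Sequence XML.
#' @return A [sequence_block()]. Case of the residues is preserved.
#' @export
parse_sequence <- function(xml_text) {
  doc <- read_xml_checked(xml_text)
  node <- xml2::xml_find_first(doc, ".//SEQUENCE | .//DNA/..")
  if (inherits(node, "xml_missing"))
    stop_schema("sequence document has no SEQUENCE element")
  dna <- xml2::xml_find_first(node, "./DNA")
  residues <- xml2::xml_text(if (inherits(dna, "xml_missing")) node else dna)
  residues <- gsub("[[:space:]]", "", residues)
  segment <- genomic_segment(
    segment_id = xml2::xml_attr(node, "id"),
    start = num_or_na(xml2::xml_attr(node, "start")),
    stop = num_or_na(xml2::xml_attr(node, "stop")),
    version = xml_attr_or_na(node, "version")
  )
  sequence_block(segment, residues)
}
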