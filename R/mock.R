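# Deterministic synthetic DAS source. Generates chromosomes with annotated
# features of several classes and emits them as DAS 1.53 XML, so the whole
# client stack runs and is testable with no live server. One RNG stream per
# spec, consumed in documented order (per segment: residues, then each
# feature class in declared order); identical seeds give identical genomes.
# Adding a class or segment changes the draws of everything after it in that
# order — cross-version draw stability is not guaranteed, only determinism
# for a fixed spec.

#' Describe one synthetic feature class
#'
#' @param type_id Feature type (e.g. `"gene"`).
#' @param count Features of this class per segment.
#' @param min_len,max_len Length range in bp; lengths are drawn log-uniform
#'   over `[min_len, max_len]` (feature sizes span orders of magnitude, from
#'   single-base variants to megabase genes — a heavy-tailed draw on the log
#'   scale emulates that).
#' @param scored Draw a uniform `[0,1]` score per feature?
#' @param stranded Draw orientation uniformly from forward/reverse
#'   (otherwise unstranded)?
#' @param grouped_fraction Fraction of features assigned shared group ids in
#'   runs of 2-5 (gene-like transcript groups).
#' @param type_category DAS type category (drives default styling).
#' @return A `feature_class` list.
#' @export
feature_class <- function(type_id, count, min_len, max_len, scored = FALSE,
                          stranded = FALSE, grouped_fraction = 0,
                          type_category = NA_character_) {
  if (count < 0) stop_argument("count must be >= 0")
  if (min_len < 1 || max_len < min_len)
    stop_argument("need 1 <= min_len <= max_len")
  if (grouped_fraction < 0 || grouped_fraction > 1)
    stop_argument("grouped_fraction must be in [0,1]")
  structure(list(type_id = type_id, count = as.integer(count),
                 min_len = as.numeric(min_len), max_len = as.numeric(max_len),
                 scored = isTRUE(scored), stranded = isTRUE(stranded),
                 grouped_fraction = as.numeric(grouped_fraction),
                 type_category = as.character(type_category)),
            class = "feature_class")
}

#' Specify a synthetic genome
#'
#' @param seed Integer RNG seed; the whole genome is a deterministic
#'   function of the spec including this seed.
#' @param segments Named numeric vector: segment id -> length in bp.
#' @param classes List of [feature_class()]s.
#' @param title,coordinate_system Source metadata for the emitted sources
#'   document.
#' @return A `mock_genome_spec`.
#' @export
mock_genome_spec <- function(seed = 42,
                             segments = c(chr1 = 2e6, chr2 = 1e6),
                             classes = default_feature_classes(),
                             title = "Synthetic annotation source",
                             coordinate_system = "synthetic-1.0") {
  if (!length(segments) || is.null(names(segments)) || any(!nzchar(names(segments))))
    stop_argument("segments must be a named vector of lengths")
  if (any(segments < 1)) stop_argument("segment lengths must be >= 1")
  structure(list(seed = as.integer(seed), segments = segments,
                 classes = classes, title = title,
                 coordinate_system = coordinate_system),
            class = "mock_genome_spec")
}

#' Default synthetic feature classes
#'
#' A small, genome-like mixture per segment: sparse long gene models
#' (stranded, grouped into transcript-like runs), denser exon-scale
#' features, unstranded scored repeats, and single-base scored variants.
#'
#' @return List of [feature_class()]s.
#' @export
default_feature_classes <- function() {
  list(
    feature_class("gene", 300, 500, 50000, stranded = TRUE,
                  grouped_fraction = 0.5, type_category = "transcription"),
    feature_class("exon", 1500, 100, 1000, stranded = TRUE,
                  grouped_fraction = 0.8, type_category = "transcription"),
    feature_class("repeat", 2000, 100, 5000, scored = TRUE,
                  type_category = "repeat_region"),
    feature_class("snv", 1000, 1, 1, scored = TRUE,
                  type_category = "variation")
  )
}

#' Draw from a log-uniform distribution
#'
#' `exp(U)` with `U` uniform on `[log(min), log(max)]`; the mean is
#' `(max - min) / log(max / min)` for `min < max`.
#'
#' @param n Number of draws.
#' @param min,max Range (`0 < min <= max`).
#' @return Numeric vector of length `n`.
#' @export
rloguniform <- function(n, min, max) {
  if (min <= 0 || max < min) stop_argument("need 0 < min <= max")
  if (min == max) return(rep(as.numeric(min), n))
  exp(stats::runif(n, log(min), log(max)))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate the synthetic genome for a spec
#'
#' Deterministic in the spec: residues are i.i.d. uniform over A/C/G/T;
#' each class contributes exactly `count` features per segment with starts
#' uniform over the positions where the feature still fits, log-uniform
#' lengths (rounded, min 1 bp), uniform `[0,1]` scores when scored, uniform
#' forward/reverse orientation when stranded, and a `grouped_fraction` share
#' of features sharing group ids in runs of 2-5.
#'
#' @param spec A [mock_genome_spec()].
#' @param with_residues Generate residues? (Skipping them is cheaper when
#'   only features are needed.)
#' @return A `mock_genome`: list with `spec`, `segments` (each with
#'   `segment` ([genomic_segment()]), `features` ([das_features()]) and
#'   `residues`).
#' @export
generate_annotation_set <- function(spec, with_residues = TRUE) {
  stopifnot(inherits(spec, "mock_genome_spec"))
  with_seed(spec$seed, {
    segs <- lapply(names(spec$segments), function(seg_id) {
      len <- spec$segments[[seg_id]]
      residues <- if (with_residues)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
      else NA_character_
      feats <- lapply(spec$classes, function(cl)
        generate_class(cl, seg_id, len))
      feats <- do.call(rbind, feats)
      if (is.null(feats)) feats <- empty_features()
      rownames(feats) <- NULL
      class(feats) <- c("das_features", "data.frame")
      list(segment = genomic_segment(seg_id, 1, len, total_length = len),
           features = feats, residues = residues)
    })
    names(segs) <- names(spec$segments)
    structure(list(spec = spec, segments = segs), class = "mock_genome")
  })
}

generate_class <- function(cl, seg_id, seg_len) {
  n <- cl$count
  if (n == 0) return(NULL)
  lens <- pmin(pmax(1, round(rloguniform(n, cl$min_len, cl$max_len))), seg_len)
  starts <- floor(stats::runif(n, min = 1, max = seg_len - lens + 1 + 1))
  starts <- pmin(pmax(1, starts), seg_len - lens + 1)
  scores <- if (cl$scored) stats::runif(n) else rep(NA_real_, n)
  orient <- if (cl$stranded)
    c("forward", "reverse")[1 + (stats::runif(n) < 0.5)]
  else rep("unstranded", n)
  group_id <- rep(NA_character_, n)
  n_grouped <- round(n * cl$grouped_fraction)
  i <- 1; g <- 0
  while (i <= n_grouped) {
    run <- min(sample(2:5, 1), n_grouped - i + 1)
    g <- g + 1
    group_id[i:(i + run - 1)] <- sprintf("%s_%s_grp%03d", seg_id, cl$type_id, g)
    i <- i + run
  }
  ids <- sprintf("%s_%s_%05d", seg_id, cl$type_id, seq_len(n))
  das_features(
    feature_id = ids, label = ids, type_id = cl$type_id,
    type_category = cl$type_category, method = "synthetic",
    start = starts, stop = starts + lens - 1, score = scores,
    orientation = orient, group_id = group_id
  )
}

#' @export
print.mock_genome <- function(x, ...) {
  cat(sprintf("<mock_genome> seed %d, %d segment(s)\n", x$spec$seed,
              length(x$segments)))
  for (s in x$segments)
    cat(sprintf("  %s: %s bp, %d features\n", s$segment$segment_id,
                format(segment_span(s$segment), big.mark = ","),
                nrow(s$features)))
  invisible(x)
}

# ---- XML emitters ---------------------------------------------------------
# Built by string assembly (fast for 10^4+ features); text content and
# attribute values are XML-escaped. The documents round-trip losslessly
# through the das_protocol parsers for every modeled field.

xesc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

opt_attr <- function(name, value) {
  ifelse(is.na(value), "", sprintf(' %s="%s"', name, xesc(value)))
}

#' Emit a DAS features document
#'
#' @param segment The [genomic_segment()] window the document covers.
#' @param features A [das_features()] table.
#' @param href Request URL echoed in the document.
#' @return DAS features XML text.
#' @export
emit_features_xml <- function(segment, features, href = "mock://features") {
  stopifnot(inherits(segment, "genomic_segment"))
  n <- nrow(features)
  body <- if (n == 0) character() else {
    score_txt <- ifelse(is.na(features$score), "-",
                        formatC(features$score, format = "g", digits = 15))
    phase_txt <- ifelse(is.na(features$phase), "-",
                        as.character(features$phase))
    orient_txt <- orientation_to_symbol(features$orientation)
    notes <- vapply(features$notes, function(nn)
      paste(sprintf("<NOTE>%s</NOTE>", xesc(nn)), collapse = ""), character(1))
    method_xml <- ifelse(is.na(features$method), "",
                         sprintf('<METHOD id="%s">%s</METHOD>',
                                 xesc(features$method), xesc(features$method)))
    sprintf(paste0(
      '<FEATURE id="%s"%s>',
      '<TYPE id="%s"%s>%s</TYPE>',
      "%s",
      "<START>%s</START><END>%s</END>",
      "<SCORE>%s</SCORE><ORIENTATION>%s</ORIENTATION><PHASE>%s</PHASE>",
      "%s%s%s</FEATURE>"),
      xesc(features$feature_id), opt_attr("label", features$label),
      xesc(features$type_id), opt_attr("category", features$type_category),
      xesc(features$type_id),
      method_xml,
      format(features$start, scientific = FALSE, trim = TRUE),
      format(features$stop, scientific = FALSE, trim = TRUE),
      score_txt, orient_txt, phase_txt,
      ifelse(is.na(features$group_id), "",
             sprintf('<GROUP id="%s"/>', xesc(features$group_id))),
      ifelse(is.na(features$link), "",
             sprintf('<LINK href="%s"/>', xesc(features$link))),
      notes)
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         "<DASGFF>\n",
         sprintf('<GFF version="1.0" href="%s">\n', xesc(href)),
         sprintf('<SEGMENT id="%s" start="%s" stop="%s"%s>\n',
                 xesc(segment$segment_id),
                 format(segment$start, scientific = FALSE),
                 format(segment$stop, scientific = FALSE),
                 opt_attr("version", segment$version)),
         paste(body, collapse = "\n"), if (n) "\n" else "",
         "</SEGMENT>\n</GFF>\n</DASGFF>\n")
}

#' Emit a DAS sequence document
#'
#' @param segment The [genomic_segment()] window.
#' @param residues Residue string; its length must equal the window span.
#' @return DAS sequence XML text.
#' @export
emit_sequence_xml <- function(segment, residues) {
  stopifnot(inherits(segment, "genomic_segment"))
  block <- sequence_block(segment, residues)   # validates length/alphabet
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         "<DASSEQUENCE>\n",
         sprintf('<SEQUENCE id="%s" start="%s" stop="%s" moltype="DNA" version="%s">',
                 xesc(segment$segment_id),
                 format(segment$start, scientific = FALSE),
                 format(segment$stop, scientific = FALSE),
                 xesc(ifelse(is.na(segment$version), "1.0", segment$version))),
         block$residues,
         "</SEQUENCE>\n</DASSEQUENCE>\n")
}

#' Emit a DAS entry_points document
#'
#' @param spec A [mock_genome_spec()].
#' @param href Request URL echoed in the document.
#' @return DAS entry points XML text.
#' @export
emit_entry_points_xml <- function(spec, href = "mock://entry_points") {
  segs <- sprintf('<SEGMENT id="%s" start="1" stop="%s" orientation="+">%s</SEGMENT>',
                  xesc(names(spec$segments)),
                  format(unname(spec$segments), scientific = FALSE),
                  xesc(names(spec$segments)))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<DASEP>\n<ENTRY_POINTS href="%s" version="1.0">\n', xesc(href)),
         paste(segs, collapse = "\n"),
         "\n</ENTRY_POINTS>\n</DASEP>\n")
}

#' Emit a DAS sources document
#'
#' @param spec A [mock_genome_spec()].
#' @param base_url Base URL under which the source is being served.
#' @return DAS sources XML text.
#' @export
emit_sources_xml <- function(spec, base_url = "http://localhost/das/mock") {
  caps <- c("sources", "entry_points", "sequence", "features", "types")
  cap_xml <- paste(sprintf('<CAPABILITY type="das1:%s" query_uri="%s/%s"/>',
                           caps, xesc(base_url), caps), collapse = "\n")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         "<SOURCES>\n",
         sprintf('<SOURCE uri="%s" title="%s">\n', xesc(base_url),
                 xesc(spec$title)),
         sprintf('<VERSION uri="%s" created="2011-01-01">\n', xesc(base_url)),
         sprintf('<COORDINATES authority="%s" source="Chromosome">%s</COORDINATES>\n',
                 xesc(spec$coordinate_system), xesc(spec$coordinate_system)),
         cap_xml,
         "\n</VERSION>\n</SOURCE>\n</SOURCES>\n")
}

#' Emit the DAS error document for an unknown segment
#'
#' @param segment_id The unknown segment id.
#' @return DAS features XML with an `ERRORSEGMENT` element.
#' @export
emit_error_segment_xml <- function(segment_id) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<DASGFF>\n<GFF version="1.0" href="mock://error">\n',
         sprintf('<ERRORSEGMENT id="%s"/>\n', xesc(segment_id)),
         "</GFF>\n</DASGFF>\n")
}

#' Emit a DAS types document
#'
#' @param genome A generated `mock_genome`.
#' @return DAS types XML listing per-segment feature type counts.
#' @export
emit_types_xml <- function(genome) {
  seg_xml <- vapply(genome$segments, function(s) {
    tab <- table(s$features$type_id)
    types <- sprintf('<TYPE id="%s">%d</TYPE>', xesc(names(tab)),
                     as.integer(tab))
    sprintf('<SEGMENT id="%s" start="1" stop="%s" version="1.0">\n%s\n</SEGMENT>',
            xesc(s$segment$segment_id),
            format(s$segment$stop, scientific = FALSE),
            paste(types, collapse = "\n"))
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<DASTYPES>\n<GFF version="1.0" href="mock://types">\n',
         paste(seg_xml, collapse = "\n"),
         "\n</GFF>\n</DASTYPES>\n")
}
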