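# Local DAS server over the synthetic genome. Single-threaded, blocking,
# speaks enough HTTP/1.0 for the GET-only DAS command set; meant for
# offline development, demos and end-to-end tests, not production hosting.

# Answer one DAS request path (relative to the base URL, e.g.
# "features?segment=chr1:1,1000"). Shared by the HTTP server and the
# in-process mock transport so both give byte-identical answers.
mock_respond <- function(genome, rel_path, base_url) {
  parts <- strsplit(rel_path, "?", fixed = TRUE)[[1]]
  command <- parts[1]
  query <- if (length(parts) > 1) parts[2] else ""
  params <- parse_query(query)

  ok <- function(body) list(status = 200L, body = body,
                            content_type = "text/xml")
  if (command == "sources")
    return(ok(emit_sources_xml(genome$spec, base_url)))
  if (command == "entry_points")
    return(ok(emit_entry_points_xml(genome$spec,
                                    paste0(base_url, "/entry_points"))))
  if (command == "types")
    return(ok(emit_types_xml(genome)))
  if (!command %in% c("features", "sequence"))
    return(list(status = 400L, body = sprintf("unknown command: %s", command),
                content_type = "text/plain"))

  seg_spec <- params[["segment"]]
  if (is.null(seg_spec))
    return(list(status = 400L, body = "missing segment parameter",
                content_type = "text/plain"))
  m <- regmatches(seg_spec,
                  regexec("^([^:]+)(:([0-9]+),([0-9]+))?$", seg_spec))[[1]]
  if (!length(m))
    return(list(status = 400L, body = "malformed segment parameter",
                content_type = "text/plain"))
  seg_id <- m[2]
  seg <- genome$segments[[seg_id]]
  if (is.null(seg)) return(ok(emit_error_segment_xml(seg_id)))
  if (nzchar(m[3])) {
    start <- as.numeric(m[4]); stop <- as.numeric(m[5])
    if (start > stop || start < 1 || stop > segment_span(seg$segment))
      return(list(status = 400L, body = "segment range out of bounds",
                  content_type = "text/plain"))
  } else {
    start <- 1; stop <- segment_span(seg$segment)
  }
  window <- genomic_segment(seg_id, start, stop,
                            total_length = segment_span(seg$segment))
  if (command == "sequence") {
    if (is.na(seg$residues))
      return(list(status = 400L, body = "no sequence available",
                  content_type = "text/plain"))
    return(ok(emit_sequence_xml(window, substr(seg$residues, start, stop))))
  }
  # features: everything overlapping (not just contained in) the range
  keep <- seg$features$stop >= start & seg$features$start <= stop
  feats <- seg$features[keep, , drop = FALSE]
  rownames(feats) <- NULL
  class(feats) <- c("das_features", "data.frame")
  ok(emit_features_xml(window, feats,
                       href = paste0(base_url, "/features?segment=", seg_spec)))
}

parse_query <- function(query) {
  if (!nzchar(query)) return(list())
  pairs <- strsplit(strsplit(query, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(pairs, function(p) utils::URLdecode(if (length(p) > 1) p[2] else ""))
  names(vals) <- vapply(pairs, `[[`, character(1), 1)
  vals
}

#' Serve a synthetic genome over local HTTP (blocking)
#'
#' Answers the DAS commands `sources`, `entry_points`, `types`, `sequence`
#' and `features` (with segment ranges; a range query returns the features
#' overlapping the range) under `http://127.0.0.1:<port>/das/mock`. Unknown
#' segments get a DAS error document; malformed requests get HTTP 400.
#' Blocks the calling process; use [start_mock_das_server()] to run it in a
#' child process.
#'
#' @param spec A [mock_genome_spec()], or an already generated
#'   `mock_genome`.
#' @param port TCP port to listen on.
#' @param max_requests Stop after this many requests (default `Inf`).
#' @param delay_seconds Optional fixed artificial delay per request (for
#'   exercising timeout handling).
#' @return Number of requests served, invisibly (when `max_requests` is
#'   finite).
#' @export
das_serve <- function(spec, port, max_requests = Inf, delay_seconds = 0) {
  genome <- if (inherits(spec, "mock_genome")) spec
            else generate_annotation_set(spec)
  base_url <- sprintf("http://127.0.0.1:%d/das/mock", as.integer(port))
  srv <- serverSocket(as.integer(port))
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    served <- served + 1
    tryCatch({
      req_line <- readLines(con, n = 1, warn = FALSE)
      repeat {
        line <- readLines(con, n = 1, warn = FALSE)
        if (!length(line) || !nzchar(line)) break
      }
      m <- regmatches(req_line,
                      regexec("^GET +([^ ]+) +HTTP", req_line))[[1]]
      resp <- if (!length(m)) {
        list(status = 400L, body = "bad request", content_type = "text/plain")
      } else {
        path <- m[2]
        prefix <- "/das/mock/"
        if (startsWith(path, prefix))
          mock_respond(genome, substring(path, nchar(prefix) + 1), base_url)
        else list(status = 404L, body = "not found",
                  content_type = "text/plain")
      }
      if (delay_seconds > 0) Sys.sleep(delay_seconds)
      body_raw <- charToRaw(resp$body)
      status_text <- c("200" = "OK", "400" = "Bad Request",
                       "404" = "Not Found")[as.character(resp$status)]
      writeLines(c(sprintf("HTTP/1.0 %d %s", resp$status, status_text),
                   sprintf("Content-Type: %s", resp$content_type),
                   sprintf("Content-Length: %d", length(body_raw)),
                   "X-DAS-Version: DAS/1.53",
                   sprintf("X-DAS-Status: %d", resp$status),
                   "Connection: close", ""), con, sep = "\r\n")
      writeBin(body_raw, con)
      flush(con)
    }, error = function(e) NULL)
    close(con)
  }
  invisible(served)
}

#' Start the mock DAS server in a background process
#'
#' Spawns an `Rscript` child running [das_serve()] and waits until the
#' endpoint answers. Requires the processx package.
#'
#' @param spec A [mock_genome_spec()].
#' @param port Port; a random high port is chosen when `NULL`.
#' @param timeout_seconds How long to wait for the server to come up.
#' @return A handle: list with `base_url`, `port`, `process`. Stop it with
#'   [stop_mock_das_server()].
#' @export
start_mock_das_server <- function(spec, port = NULL, timeout_seconds = 30) {
  if (!requireNamespace("processx", quietly = TRUE))
    stop_argument("start_mock_das_server requires the processx package")
  spec_file <- tempfile(fileext = ".rds")
  saveRDS(spec, spec_file)
  for (attempt in 1:5) {
    p <- if (is.null(port)) sample(20000:40000, 1) else port
    child <- processx::process$new(
      file.path(R.home("bin"), "Rscript"),
      c("-e", sprintf(
        "dastrack::das_serve(readRDS('%s'), port = %d)", spec_file, p)),
      stdout = "|", stderr = "|")
    base_url <- sprintf("http://127.0.0.1:%d/das/mock", p)
    deadline <- Sys.time() + timeout_seconds
    while (Sys.time() < deadline && child$is_alive()) {
      up <- tryCatch({
        r <- http_get(paste0(base_url, "/sources"), timeout_seconds = 2)
        r$status == 200L
      }, error = function(e) FALSE)
      if (up)
        return(structure(list(base_url = base_url, port = p, process = child,
                              spec_file = spec_file),
                         class = "mock_das_server"))
      Sys.sleep(0.2)
    }
    child$kill()
    if (!is.null(port)) break
  }
  stop_network("mock DAS server failed to start")
}

#' Stop a background mock DAS server
#'
#' @param handle Handle from [start_mock_das_server()].
#' @return `TRUE`, invisibly.
#' @export
stop_mock_das_server <- function(handle) {
  if (handle$process$is_alive()) handle$process$kill()
  unlink(handle$spec_file)
  invisible(TRUE)
}

#' @export
print.mock_das_server <- function(x, ...) {
  cat(sprintf("<mock_das_server> %s (%s)\n", x$base_url,
              if (x$process$is_alive()) "running" else "stopped"))
  invisible(x)
}
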