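# Transport seam. Everything that fetches a DAS document goes through a
# transport: a function(url) returning list(status, body). The default
# transport speaks plain HTTP/1.0 over a socket with a configurable timeout
# (default 30 s); tests and offline use inject canned or in-process
# transports through the same seam. Timeouts raise a distinct retryable
# condition ("das_timeout_error") — the expected failure mode when
# requesting large regions of very dense tracks.

parse_http_url <- function(url) {
  m <- regmatches(url, regexec("^http://([^/:]+)(:([0-9]+))?(/.*)?$", url))[[1]]
  if (!length(m)) stop_argument(sprintf("not an http:// URL: %s", url))
  list(host = m[2],
       port = if (nzchar(m[4])) as.integer(m[4]) else 80L,
       path = if (nzchar(m[5])) m[5] else "/")
}

#' Perform a plain HTTP GET
#'
#' Minimal HTTP/1.0 client over a blocking socket. Used by the default
#' transport; exported for direct use against local DAS endpoints.
#'
#' @param url An `http://` URL.
#' @param timeout_seconds Socket timeout; exceeding it raises a retryable
#'   timeout error.
#' @return List with `status` (integer) and `body` (string).
#' @export
http_get <- function(url, timeout_seconds = 30) {
  u <- parse_http_url(url)
  con <- tryCatch(
    socketConnection(u$host, u$port, open = "r+b", blocking = TRUE,
                     timeout = timeout_seconds),
    error = function(e) stop_network(sprintf("cannot connect to %s:%d: %s",
                                             u$host, u$port,
                                             conditionMessage(e))),
    warning = function(w) stop_network(sprintf("cannot connect to %s:%d: %s",
                                               u$host, u$port,
                                               conditionMessage(w)))
  )
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("GET %s HTTP/1.0", u$path),
               sprintf("Host: %s", u$host),
               "Connection: close", ""), con, sep = "\r\n")
  flush(con)
  status_line <- readLines(con, n = 1, warn = FALSE)
  if (!length(status_line) || !nzchar(status_line))
    stop_timeout(sprintf("no response from %s within %g s (retry may succeed)",
                         url, timeout_seconds))
  status <- suppressWarnings(as.integer(sub("^HTTP/[0-9.]+ +([0-9]+).*$", "\\1",
                                            status_line)))
  if (is.na(status)) stop_network(sprintf("malformed HTTP response: %s",
                                          status_line))
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line) || !nzchar(line)) break
  }
  body <- paste(readLines(con, warn = FALSE), collapse = "\n")
  list(status = status, body = body)
}

#' The default HTTP transport
#'
#' @param timeout_seconds Per-request socket timeout.
#' @return A transport function `function(url) -> list(status, body)`.
#' @export
http_transport <- function(timeout_seconds = 30) {
  force(timeout_seconds)
  function(url) http_get(url, timeout_seconds = timeout_seconds)
}

#' A canned transport serving fixed responses (for tests and offline use)
#'
#' @param responses Named character vector or list, URL -> body.
#' @return A transport function; unknown URLs get status 404.
#' @export
canned_transport <- function(responses) {
  force(responses)
  function(url) {
    if (!url %in% names(responses)) return(list(status = 404L, body = ""))
    list(status = 200L, body = responses[[url]])
  }
}

#' An in-process transport answering DAS requests from a synthetic genome
#'
#' Serves the same responses as [das_serve()] without any socket: requests
#' to `<base_url>/<command>` are answered straight from the generated
#' genome. This is the offline default for the high-level client.
#'
#' @param genome A `mock_genome` from [generate_annotation_set()].
#' @param base_url Base URL this transport pretends to serve.
#' @return A transport function.
#' @export
mock_transport <- function(genome, base_url = "mock://genome") {
  force(genome); force(base_url)
  base_url <- sub("/+$", "", base_url)
  function(url) {
    if (!startsWith(url, paste0(base_url, "/")))
      return(list(status = 404L, body = ""))
    rel <- substring(url, nchar(base_url) + 2)
    resp <- mock_respond(genome, rel, base_url)
    list(status = resp$status, body = resp$body)
  }
}

#' Fetch and return a raw DAS document
#'
#' Builds the request with [build_request()] and performs it through the
#' given transport. Non-200 responses raise a network error.
#'
#' @param source A [das_source_ref()].
#' @param command DAS command.
#' @param segment_id,start,stop Optional segment/range (see
#'   [build_request()]).
#' @param transport A transport function; default plain HTTP.
#' @return The response body (XML text).
#' @export
das_fetch <- function(source, command, segment_id = NULL, start = NULL,
                      stop = NULL, transport = http_transport()) {
  url <- build_request(source, command, segment_id, start, stop)
  resp <- transport(url)
  if (resp$status != 200L)
    stop_network(sprintf("HTTP %d for %s", resp$status, url))
  resp$body
}
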