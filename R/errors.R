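# Condition classes used across the package. All are subclasses of
# "das_error" so callers can catch everything from this package at once;
# "das_timeout_error" is additionally tagged retryable.

das_condition <- function(subclass, message, call = sys.call(-1), data = list()) {
  structure(
    class = c(subclass, "das_error", "error", "condition"),
    list(message = message, call = call, data = data)
  )
}

stop_das <- function(subclass, message, data = list()) {
  stop(das_condition(subclass, message, call = sys.call(-1), data = data))
}

#' Stop with a capability error (command not offered by a source)
#' @noRd
stop_capability <- function(message, ...) stop_das("das_capability_error", message, list(...))

stop_argument   <- function(message, ...) stop_das("das_argument_error", message, list(...))
stop_parse      <- function(message, ...) stop_das("das_parse_error", message, list(...))
stop_schema     <- function(message, ...) stop_das("das_schema_error", message, list(...))
stop_validation <- function(message, ...) stop_das("das_validation_error", message, list(...))
stop_version    <- function(message, ...) stop_das("das_version_error", message, list(...))
stop_network    <- function(message, ...) stop_das("das_network_error", message, list(...))
stop_container  <- function(message, ...) stop_das("das_container_error", message, list(...))

stop_timeout <- function(message, ...) {
  cond <- das_condition(c("das_timeout_error", "das_retryable_error"),
                        message, call = sys.call(-1), data = list(...))
  stop(cond)
}

#' Test whether a condition signals a retryable transport failure
#'
#' Timeouts raised by the HTTP transport are retryable: the request was valid,
#' the server was just slow (the classic failure mode when requesting large
#' regions of very dense tracks).
#'
#' @param cond A condition object.
#' @return `TRUE` if retrying the same request may succeed.
#' @export
is_retryable_error <- function(cond) inherits(cond, "das_retryable_error")
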