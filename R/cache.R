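# In-memory interval cache. Keyed by (source_url, segment_id, tier_label);
# each entry records which bases are held as a normalized interval set
# (sorted, disjoint, adjacent runs merged) together with the payload fetched
# for each inserted interval. plan_fetch() splits a wanted range into the
# sub-ranges already held and the sub-ranges that must still be fetched, so a
# base fetched once is never fetched again under the same key. Eviction is
# whole-entry: TTL-expired entries first, then least-recently-used entries
# until the byte budget is met. Recency is a monotonic counter bumped on
# plan_fetch hits and inserts, so LRU order is deterministic without
# wall-clock time.

# ---- interval sets --------------------------------------------------------
# Normal form: two-column numeric matrix (start, stop), 1-based inclusive,
# sorted, pairwise disjoint, adjacent intervals merged. IRanges does the set
# algebra; the matrix form keeps the public surface plain-R.

iset <- function(start = numeric(), stop = numeric()) {
  if (length(start) == 0)
    return(structure(matrix(numeric(), ncol = 2,
                            dimnames = list(NULL, c("start", "stop"))),
                     class = "interval_set"))
  if (any(stop < start)) stop_argument("interval stop < start")
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = stop))
  structure(cbind(start = IRanges::start(r), stop = IRanges::end(r)),
            class = "interval_set")
}

as_iranges <- function(is) IRanges::IRanges(start = is[, "start"], end = is[, "stop"])

from_iranges <- function(r) {
  structure(cbind(start = IRanges::start(r), stop = IRanges::end(r)),
            class = "interval_set")
}

iset_union <- function(a, b)
  from_iranges(IRanges::reduce(c(as_iranges(a), as_iranges(b))))

iset_intersect <- function(a, b)
  from_iranges(IRanges::reduce(IRanges::intersect(as_iranges(a), as_iranges(b)),
                               min.gapwidth = 1L))

iset_diff <- function(a, b)
  from_iranges(IRanges::setdiff(as_iranges(a), as_iranges(b)))

iset_total <- function(a) if (nrow(a) == 0) 0 else sum(a[, "stop"] - a[, "start"] + 1)

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s), %s bases\n", nrow(x),
              format(iset_total(x), big.mark = ",")))
  if (nrow(x)) print(unclass(x))
  invisible(x)
}

# ---- cache ----------------------------------------------------------------

#' Build a cache key
#'
#' @param source_url DAS source base URL.
#' @param segment_id Segment name.
#' @param tier_label Tier label from [tier_label()] (e.g. `"individual"`,
#'   `"bin:1000"`).
#' @return An object of class `cache_key`.
#' @export
cache_key <- function(source_url, segment_id, tier_label) {
  if (!nzchar(source_url) || !nzchar(segment_id) || !nzchar(tier_label))
    stop_argument("cache key fields must be non-empty")
  structure(list(source_url = source_url, segment_id = segment_id,
                 tier_label = tier_label), class = "cache_key")
}

key_string <- function(key) paste(key$source_url, key$segment_id,
                                  key$tier_label, sep = "|")

#' Create an empty interval cache
#'
#' @param budget_bytes Byte budget for LRU eviction (default 256 MiB, a
#'   typical in-memory footprint for interactive browsing).
#' @param ttl_seconds Optional entry lifetime in seconds (default `Inf`:
#'   no expiry; a server-role cache would use a short TTL such as 300 s so
#'   upstream updates propagate).
#' @return A `das_cache` object (an environment; mutated in place).
#' @export
das_cache <- function(budget_bytes = 256 * 1024^2, ttl_seconds = Inf) {
  if (budget_bytes < 0) stop_argument("budget_bytes must be >= 0")
  env <- new.env(parent = emptyenv())
  env$entries <- list()     # key_string -> entry
  env$clock <- 0            # monotonic recency counter
  env$budget_bytes <- budget_bytes
  env$ttl_seconds <- ttl_seconds
  env$stats <- list(hits = 0, misses = 0, inserted_bases = 0, fetched_bases = 0)
  class(env) <- "das_cache"
  env
}

#' @export
print.das_cache <- function(x, ...) {
  cat(sprintf("<das_cache> %d entr%s, %s / %s bytes\n", length(x$entries),
              if (length(x$entries) == 1) "y" else "ies",
              format(cache_total_size(x), big.mark = ","),
              format(x$budget_bytes, big.mark = ",")))
  invisible(x)
}

new_entry <- function(key, now) {
  list(key = key, held = iset(), payloads = list(), last_access = 0,
       inserted_at = now, size_bytes = 0)
}

#' Total payload bytes currently cached
#' @param cache A [das_cache()].
#' @return Total `size_bytes` over all entries.
#' @export
cache_total_size <- function(cache) {
  if (!length(cache$entries)) return(0)
  sum(vapply(cache$entries, function(e) e$size_bytes, numeric(1)))
}

#' Split a wanted range into covered and missing parts
#'
#' The covered part is already held under `key` and need not be fetched
#' again; the missing part must be. Together they partition the wanted range
#' exactly. A non-empty covered part counts as a cache hit and bumps the
#' entry's recency.
#'
#' @param cache A [das_cache()].
#' @param key A [cache_key()].
#' @param start,stop Wanted range, 1-based inclusive.
#' @return List with `covered` and `missing` interval sets (two-column
#'   matrices of start/stop).
#' @export
plan_fetch <- function(cache, key, start, stop) {
  if (start > stop) stop_argument("plan_fetch: start must be <= stop")
  want <- iset(start, stop)
  ks <- key_string(key)
  entry <- cache$entries[[ks]]
  if (is.null(entry)) {
    cache$stats$misses <- cache$stats$misses + 1
    return(list(covered = iset(), missing = want))
  }
  covered <- iset_intersect(want, entry$held)
  missing <- iset_diff(want, entry$held)
  if (nrow(covered)) {
    cache$clock <- cache$clock + 1
    entry$last_access <- cache$clock
    cache$entries[[ks]] <- entry
    cache$stats$hits <- cache$stats$hits + 1
  } else {
    cache$stats$misses <- cache$stats$misses + 1
  }
  list(covered = covered, missing = missing)
}

#' Insert a fetched payload into the cache
#'
#' Records that `[start, stop]` is now held under `key`, stores the payload
#' for that interval, bumps recency, and evicts to budget. The payload's tier
#' must match the key's tier label: a `summary_bins` payload belongs to a
#' `bin:<w>` key and a `das_features` payload to a `sequence`/`individual`
#' key (a `sequence_block` is accepted for `sequence`).
#'
#' @param cache A [das_cache()].
#' @param key A [cache_key()].
#' @param start,stop Interval the payload covers (1-based inclusive).
#' @param payload The fetched payload.
#' @param now Wall-clock time in seconds (for TTL accounting); defaults to
#'   `Sys.time()`.
#' @return The cache, invisibly.
#' @export
cache_insert <- function(cache, key, start, stop, payload,
                         now = as.numeric(Sys.time())) {
  if (start > stop) stop_argument("cache_insert: start must be <= stop")
  is_bin_key <- grepl("^bin:", key$tier_label)
  is_bin_payload <- inherits(payload, "summary_bins")
  if (is_bin_key != is_bin_payload)
    stop_argument(sprintf("payload kind does not match tier '%s'", key$tier_label))
  ks <- key_string(key)
  entry <- cache$entries[[ks]]
  if (is.null(entry)) entry <- new_entry(key, now)
  entry$held <- iset_union(entry$held, iset(start, stop))
  pname <- sprintf("%s-%s", format(start, scientific = FALSE),
                   format(stop, scientific = FALSE))
  entry$payloads[[pname]] <- list(start = start, stop = stop, payload = payload)
  entry$size_bytes <- sum(vapply(entry$payloads,
                                 function(p) payload_bytes(p$payload), numeric(1)))
  cache$clock <- cache$clock + 1
  entry$last_access <- cache$clock
  cache$entries[[ks]] <- entry
  cache$stats$inserted_bases <- cache$stats$inserted_bases + (stop - start + 1)
  cache_evict(cache, now = now)
  invisible(cache)
}

payload_bytes <- function(payload) {
  if (inherits(payload, "sequence_block")) return(nchar(payload$residues))
  nchar(serialize_payload(payload), type = "bytes")
}

#' Evict entries to meet the byte budget
#'
#' Entries older than the TTL are dropped first; then least-recently-used
#' entries are dropped until the total size fits the budget. Surviving
#' entries are untouched.
#'
#' @param cache A [das_cache()].
#' @param budget_bytes Budget; defaults to the cache's configured budget.
#' @param now Wall-clock seconds used for TTL comparison.
#' @param ttl_seconds TTL; defaults to the cache's configured TTL.
#' @return Character vector of evicted key strings
#'   (`source|segment|tier`), invisibly empty when nothing was evicted.
#' @export
cache_evict <- function(cache, budget_bytes = cache$budget_bytes,
                        now = as.numeric(Sys.time()),
                        ttl_seconds = cache$ttl_seconds) {
  evicted <- character()
  if (is.finite(ttl_seconds) && length(cache$entries)) {
    age <- vapply(cache$entries, function(e) now - e$inserted_at, numeric(1))
    expired <- names(cache$entries)[age > ttl_seconds]
    evicted <- c(evicted, expired)
    cache$entries[expired] <- NULL
  }
  total <- cache_total_size(cache)
  while (total > budget_bytes && length(cache$entries)) {
    acc <- vapply(cache$entries, function(e) e$last_access, numeric(1))
    victim <- names(cache$entries)[which.min(acc)]
    total <- total - cache$entries[[victim]]$size_bytes
    cache$entries[[victim]] <- NULL
    evicted <- c(evicted, victim)
  }
  invisible(evicted)
}

#' Assemble the cached payload covering a window
#'
#' Concatenates the stored payload pieces under `key` that overlap
#' `[start, stop]`. Features are deduplicated by `feature_id` and returned
#' sorted by (start, stop, feature_id); bins are deduplicated by `bin_start`
#' and clipped to the pieces fetched. The window must be fully covered
#' (check with [plan_fetch()] first).
#'
#' @inheritParams plan_fetch
#' @return A `das_features` table, `summary_bins` data.frame, or the
#'   residues string for sequence payloads.
#' @export
cache_assemble <- function(cache, key, start, stop) {
  entry <- cache$entries[[key_string(key)]]
  if (is.null(entry)) stop_argument("no cache entry for key")
  missing <- iset_diff(iset(start, stop), entry$held)
  if (nrow(missing))
    stop_argument("window not fully cached; fetch missing ranges first")
  pieces <- Filter(function(p) p$stop >= start && p$start <= stop, entry$payloads)
  pieces <- pieces[order(vapply(pieces, `[[`, numeric(1), "start"))]
  payloads <- lapply(pieces, `[[`, "payload")
  first <- payloads[[1]]
  if (inherits(first, "summary_bins")) {
    bins <- do.call(rbind, lapply(payloads, as.data.frame))
    bins <- bins[!duplicated(bins$bin_start), , drop = FALSE]
    bins <- bins[bins$bin_stop >= start & bins$bin_start <= stop, , drop = FALSE]
    bins <- bins[order(bins$bin_start), , drop = FALSE]
    rownames(bins) <- NULL
    class(bins) <- c("summary_bins", "data.frame")
    return(bins)
  }
  if (inherits(first, "sequence_block")) {
    # stitch residues over the window from overlapping blocks
    out <- character(stop - start + 1)
    for (p in pieces) {
      s <- max(p$start, start); e <- min(p$stop, stop)
      if (s > e) next
      sub <- substr(p$payload$residues, s - p$start + 1, e - p$start + 1)
      out[(s - start + 1):(e - start + 1)] <- strsplit(sub, "")[[1]]
    }
    return(paste(out, collapse = ""))
  }
  feats <- do.call(rbind, payloads)
  feats <- feats[!duplicated(feats$feature_id), , drop = FALSE]
  feats <- feats[feats$stop >= start & feats$start <= stop, , drop = FALSE]
  feats <- feats[order(feats$start, feats$stop, feats$feature_id), , drop = FALSE]
  rownames(feats) <- NULL
  class(feats) <- c("das_features", "data.frame")
  feats
}
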