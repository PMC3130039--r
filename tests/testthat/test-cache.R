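# Interval cache: plan/insert semantics, normal form, LRU + TTL eviction

dummy_payload <- function(n = 1) {
  das_features(feature_id = sprintf("d%d", seq_len(n)), start = 1, stop = 1,
               type_id = "t")
}

test_that("plan_fetch splits wants into covered and missing exactly", {
  cache <- das_cache()
  key <- cache_key("http://s/das/x", "chr1", "individual")
  p <- plan_fetch(cache, key, 100, 200)
  expect_equal(nrow(p$covered), 0)
  expect_equal(unclass(p$missing), cbind(start = 100, stop = 200),
               ignore_attr = TRUE)

  cache_insert(cache, key, 100, 200, dummy_payload())
  p2 <- plan_fetch(cache, key, 150, 300)
  expect_equal(unclass(p2$covered), cbind(start = 150, stop = 200),
               ignore_attr = TRUE)
  expect_equal(unclass(p2$missing), cbind(start = 201, stop = 300),
               ignore_attr = TRUE)
})

test_that("adjacent inserts merge into one held interval", {
  cache <- das_cache()
  key <- cache_key("s", "c", "individual")
  cache_insert(cache, key, 100, 200, dummy_payload())
  cache_insert(cache, key, 201, 300, dummy_payload())
  p <- plan_fetch(cache, key, 100, 300)
  expect_equal(nrow(p$missing), 0)
  expect_equal(unclass(p$covered), cbind(start = 100, stop = 300),
               ignore_attr = TRUE)
  entry <- cache$entries[[1]]
  expect_equal(nrow(entry$held), 1)
})

test_that("payload tier must match the key tier", {
  cache <- das_cache()
  expect_error(
    cache_insert(cache, cache_key("s", "c", "bin:1000"), 1, 1000,
                 dummy_payload()),
    class = "das_argument_error")
  bins <- summarize_features(das_features(), genomic_segment("c", 1, 1000), 100)
  expect_error(
    cache_insert(cache, cache_key("s", "c", "individual"), 1, 1000, bins),
    class = "das_argument_error")
})

test_that("random insert/plan sequences match the per-base bitmap oracle", {
  seg_len <- 1e4
  for (seed in c(7, 11)) {
    set.seed(seed)
    cache <- das_cache()
    key <- cache_key("s", "c", "individual")
    bm <- bitmap_new(seg_len)
    for (step in 1:100) {
      s <- sample(seg_len, 1)
      e <- min(seg_len, s + sample(0:500, 1))
      if (runif(1) < 0.5) {
        cache_insert(cache, key, s, e, dummy_payload())
        bm <- bitmap_insert(bm, s, e)
      } else {
        plan <- plan_fetch(cache, key, s, e)
        want <- bitmap_plan(bm, s, e)
        expect_equal(iset_bases(plan$covered), want$covered_bases)
        expect_equal(iset_bases(plan$missing), want$missing_bases)
      }
      # normal form after every mutation
      held <- if (length(cache$entries)) cache$entries[[1]]$held
      if (!is.null(held) && nrow(held) > 1) {
        expect_true(all(diff(held[, "start"]) > 0))
        expect_true(all(held[-1, "start"] > held[-nrow(held), "stop"] + 1))
      }
    }
    # nothing inserted is ever reported missing
    plan <- plan_fetch(cache, key, 1, seg_len)
    expect_length(intersect(iset_bases(plan$missing), which(bm)), 0)
  }
})

test_that("LRU eviction drops the least recently used entry first", {
  cache <- das_cache(budget_bytes = .Machine$double.xmax)
  keys <- lapply(c("A", "B", "C"), function(s) cache_key("s", s, "individual"))
  for (k in keys) cache_insert(cache, k, 1, 100, dummy_payload(5))
  # nothing evicted while under budget
  expect_length(cache_evict(cache), 0)
  expect_equal(length(cache$entries), 3)

  # touch A and B so C is the oldest, then force one eviction
  plan_fetch(cache, keys[[1]], 1, 50)
  plan_fetch(cache, keys[[2]], 1, 50)
  sizes <- vapply(cache$entries, function(e) e$size_bytes, numeric(1))
  evicted <- cache_evict(cache, budget_bytes = sum(sizes) - 1)
  expect_identical(evicted, "s|C|individual")
  expect_lte(cache_total_size(cache), sum(sizes) - 1)
})

test_that("TTL expiry removes old entries before LRU kicks in", {
  cache <- das_cache(ttl_seconds = 10)
  key_old <- cache_key("s", "old", "individual")
  key_new <- cache_key("s", "new", "individual")
  cache_insert(cache, key_old, 1, 100, dummy_payload(), now = 1000)
  cache_insert(cache, key_new, 1, 100, dummy_payload(), now = 1008)
  evicted <- cache_evict(cache, now = 1011)
  expect_identical(evicted, "s|old|individual")
  expect_identical(names(cache$entries), "s|new|individual")
})

test_that("a long random event sequence reproduces a step-by-step LRU simulation", {
  set.seed(11)
  cache <- das_cache(budget_bytes = .Machine$double.xmax)
  segs <- sprintf("seg%02d", 1:8)
  # oracle state: per key, last access stamp and size
  sim <- new.env()
  sim$stamp <- 0; sim$acc <- list(); sim$size <- list()
  payload <- dummy_payload(3)
  psize <- nchar(dastrack:::serialize_payload(payload), type = "bytes")
  evictions_got <- character()
  evictions_sim <- character()
  for (step in 1:200) {
    seg <- sample(segs, 1)
    key <- cache_key("s", seg, "individual")
    ks <- paste("s", seg, "individual", sep = "|")
    if (runif(1) < 0.5) {
      cache_insert(cache, key, 1, 100, payload)
      sim$stamp <- sim$stamp + 1
      sim$acc[[ks]] <- sim$stamp
      sim$size[[ks]] <- psize   # one payload piece per key (same interval)
    } else {
      plan_fetch(cache, key, 1, 100)
      if (ks %in% names(sim$size)) {   # only hits bump recency
        sim$stamp <- sim$stamp + 1
        sim$acc[[ks]] <- sim$stamp
      }
    }
    if (step %% 20 == 0 && length(sim$size)) {
      budget <- sum(unlist(sim$size)) - 1   # force exactly one victim
      evictions_got <- c(evictions_got, cache_evict(cache, budget))
      victim <- names(which.min(unlist(sim$acc)))
      evictions_sim <- c(evictions_sim, victim)
      sim$acc[[victim]] <- NULL; sim$size[[victim]] <- NULL
    }
  }
  expect_identical(evictions_got, evictions_sim)
})

test_that("cache_assemble returns deduplicated, sorted features over the window", {
  g <- tiny_genome(5, seg_len = 5000)
  feats <- g$segments$chr1$features
  cache <- das_cache()
  key <- cache_key("s", "chr1", "individual")
  win <- function(s, e) {
    keep <- feats$stop >= s & feats$start <= e
    out <- feats[keep, , drop = FALSE]
    class(out) <- c("das_features", "data.frame")
    out
  }
  cache_insert(cache, key, 1, 3000, win(1, 3000))
  cache_insert(cache, key, 2500, 5000, win(2500, 5000))
  got <- cache_assemble(cache, key, 1, 5000)
  expect_false(any(duplicated(got$feature_id)))
  expect_features_equal(got, win(1, 5000))
  expect_true(!is.unsorted(got$start))
  expect_error(cache_assemble(cache, cache_key("s", "chr2", "individual"),
                              1, 10), class = "das_argument_error")
})
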