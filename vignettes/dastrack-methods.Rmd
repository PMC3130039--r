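---
title: "Methods: zoom tiers, interval caching, and deterministic track rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zoom tiers, interval caching, and deterministic track rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dastrack)
```

`dastrack` is a headless client for the Distributed Annotation System: it
fetches annotation and sequence documents from DAS sources, decides how much
detail a viewport can carry, caches what it has seen, and renders track
images. This vignette explains the models and the design decisions behind
each stage, including the ones where several reasonable choices existed.

## The data model

DAS coordinates are 1-based and inclusive on both ends, and the package uses
that convention in every public structure (`genomic_segment`,
`das_features`, `viewport`, cache intervals, summary bins). Any half-open
arithmetic is internal to a function and never crosses a module boundary;
this keeps the protocol edge literal and avoids off-by-one translation at
the parser and emitter.

Features are held in a classed `data.frame` with one row per feature and a
list-column of notes. Parsers are liberal about dialect — unknown XML
elements and attributes are ignored, because real DAS servers differ — but
strict about coordinates: a record with `stop < start` is rejected.
Rejection is per record, not per document: the offending `feature_id`s are
collected into a `rejected` attribute and a warning, and the remaining
records still parse. One corrupt record should not blank an entire track.

## Zoom tiers

The zoom measure is bases per pixel, `b = span / pixel_width`. Three tiers:

| tier | condition | payload |
|---|---|---|
| sequence | `b <= 1/8` | residue letters |
| individual | `1/8 < b <= T` | one glyph per feature |
| summary | `b > T` | fixed-width bins |

with both boundaries inclusive on the finer side. The sequence threshold of
8 px per base is the room a legible letter needs. The individual/summary
boundary `T` defaults to 1000 bp/px and is exposed in the configuration
(`individual_threshold`); at 1000 bp/px a 100 bp exon is a tenth of a pixel,
so drawing individual glyphs past that point costs bandwidth without adding
information. The protocol itself suggests no particular ladder; these are
package defaults, chosen once and configurable.

Summary bin widths are snapped to the smallest power of 10 at or above `b`.
Snapping trades a little resolution for cache reuse: every zoom level
between two powers of ten maps to the same bin width, so panning at nearby
zoom levels hits the same cached tier instead of refetching.

### Bin statistics

Bins tile the window left to right from `window$start`; the last bin is
truncated at the window end rather than overhanging (so bins never extend
past the segment). Each bin carries:

- `count` — features overlapping the bin, counted once per overlapped bin.
  The alternative (midpoint assignment) keeps `sum(count)` equal to the
  number of features, but makes a 2 Mb gene invisible in all but one bin at
  chromosome zoom. Overlap counting preserves the visual mass of long
  features; its conservation law — the total count equals the sum over
  features of the number of bins each overlaps — is what the tests check
  against a brute-force double loop.
- `coverage_fraction` — the fraction of bin bases covered by at least one
  feature, computed from the union of feature intervals (overlaps within a
  bin are not double-counted).
- `max_score` — the maximum score among overlapping scored features, absent
  when none carry scores.

## The interval cache

Cache keys are `(source_url, segment_id, tier_label)` where the tier label
is `"individual"`, `"sequence"`, `"residues"` or `"bin:<width>"`. Held
coverage is a normalized interval set: sorted, pairwise disjoint, with
adjacent runs merged — the normal form makes `plan_fetch()` a pair of set
operations (intersection and difference against the want), and the package
delegates that algebra to `IRanges`.

Decisions worth recording:

- **Payloads are stored at the tier's resolution.** A summary-tier insert
  stores bins, never the features that produced them, so memory scales with
  what is on screen, not with the underlying density. Consequently there is
  no cross-tier synthesis: a summary is never fabricated from cached
  individual features, and vice versa. The two caches are independent by
  design — exact semantics beat opportunistic reuse.
- **Summary wants are snapped outward to the bin grid** (anchored at base 1)
  before planning, so bins cached by different requests tile exactly and a
  narrower later request is a pure cache hit.
- **Recency is a monotonic counter**, bumped on plan hits and inserts, not
  wall-clock time: LRU order is then deterministic and testable. TTL expiry,
  which is about upstream data going stale rather than about recency, does
  use a clock; it is applied before LRU and defaults to off for the
  client-role cache (300 s is the configured default for a server-role
  deployment, long enough to absorb bursts, short enough that upstream
  updates propagate within minutes).
- **Eviction granularity is whole entries.** Evicting sub-intervals would
  require splitting stored payloads and re-accounting; per-entry eviction
  keeps the accounting exact at the cost of occasionally dropping a large
  entry when a smaller eviction would have sufficed. The default budget is
  256 MiB, an amount an interactive session can reasonably hold in memory.

## Rendering

The pixel of base `p` in viewport `[s, e]` at width `W` is
`x = floor((p - s) * W / span)` — the left edge of the base's pixel cell.
With the matching inverse `p = s + floor(x * span / W)`, the mapping is
exactly invertible whenever `span <= W`, which is what makes base-level
views precise; the tests verify the round trip exhaustively. A feature's
glyph spans from the left edge of its first visible base's cell to the right
edge of its last visible base's cell, clipped to the canvas.

Bump layout is greedy first-fit: features sorted by `(start, stop,
feature_id)` — the id as the final key makes ties deterministic — each take
the lowest row with at least `min_gap_px` pixels of clearance. First-fit is
not optimal in the number of rows, but it is the behaviour users of genome
browsers expect (earlier features sit higher) and it is linear-ish in
practice.

Ruler ticks use the smallest step from the 1-2-5 ladder that fits the tick
budget (default 10), with positions at multiples of the step — the
convention of every plotting system, chosen so labels are round numbers.

Determinism is a contract, not an accident: SVG output is written with a
canonical number format and key order, and PNG output comes from an
integer scanline rasterizer with a built-in 5x7 bitmap font. No system font,
graphics device, or floating-point-dependent anti-aliasing is involved, so
two renders of the same inputs are byte- (SVG) or pixel- (PNG) identical on
any machine. Orientation is encoded in the arrow glyph (right-pointing for
forward, left for reverse, plain box when unstranded or under 4 px wide);
histogram bars are normalized to the window maximum, so low-zoom views
always show structure rather than a flat baseline when absolute densities
are low. Labels are only drawn when the glyph is at least 30 px wide and
labels are enabled — below that they would be unreadable clutter.

Linked views (context zoom, next/previous region) are pure viewport
arithmetic in `derive_viewport()`; the center of a context view is preserved
exactly by rounding the derived start rather than flooring it.

## Sessions

"Flat text" is realized as pretty-printed JSON with a `format_version`
field and canonical key order: shareable, diffable, and rejected cleanly by
readers that encounter a version they do not know. Sessions store source
URLs, styles and viewports — never data; rebuilding a session re-fetches
(or re-serves from the synthetic source). Link-group invariants
(same-region viewers share segment and center; adjacent viewers abut
exactly) are validated both on construction and on load, so a loaded
session can never violate them.

## The synthetic source

The generator emulates the *shape* of genomic annotation a DAS client must
handle, not any particular genome. Defaults: two chromosomes (2 Mb and
1 Mb), and per segment 300 gene-scale stranded features (0.5–50 kb, half
grouped into transcript-like runs of 2–5), 1500 exon-scale stranded
features (100 bp–1 kb, 80% grouped), 2000 scored unstranded repeats
(100 bp–5 kb) and 1000 single-base scored variants. Feature lengths are
log-uniform — annotation sizes span orders of magnitude, and a draw uniform
on the log scale reproduces that heavy tail with a closed-form mean
`(b - a) / log(b / a)` the tests can check. Starts are uniform over the
positions where the feature fits; residues are i.i.d. uniform A/C/G/T.

One RNG stream per spec is consumed in documented order (per segment:
residues, then each class in declared order). Identical specs give
identical genomes; editing a spec (adding a class, reordering) changes the
draws of everything after the edit point — determinism is per spec, not a
cross-version guarantee.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: realistic length or spacing distributions
(clustering, GC bias, chromosome-arm structure), nested gene models with
exon/intron hierarchy, server dialect quirks beyond the two sources-document
forms, partial or truncated responses, and real network latency (a fixed
artificial delay is available for timeout testing). Tests passing against
the mock demonstrate protocol, cache, reduction and rendering correctness —
not robustness to every server in the wild.

## Problem sizes and tolerances

The test suite exercises round trips at about 1 100 features per genome
across ten seeds, cache behaviour with 500 random events on a 100 kb
segment against a per-base bitmap, layout on 10 000 features at 1 000 px,
and 100 random sessions; the acceptance script repeats these end to end,
including a live local HTTP server, in a few minutes on one core. These
sizes were chosen to be large enough that off-by-one and ordering bugs
cannot hide, while keeping the suite fast enough to run on every change.
Statistical checks (the log-uniform mean) use `n = 10^4` draws and a
3-standard-error band — a deterministic-seed test that fails only if the
generator is actually wrong, not from sampling noise.

## Known limitations

- DAS writeback, the 1.6E extensions, alignment/structure commands and
  stylesheet XML are out of scope; styles come from the package's own
  configuration.
- The renderer draws five glyph kinds (box, line, arrow, tick, histogram);
  continuous signal ("wiggle") tracks beyond per-bin count/coverage/max
  are not modeled.
- The HTTP server is single-threaded and blocking — a test and development
  convenience, not a deployment vehicle.
- The cache lives in memory only; there is no disk persistence.
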