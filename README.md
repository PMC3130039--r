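# dastrack

A headless R client for the **Distributed Annotation System (DAS)** — the
HTTP/XML protocol genome databases use to share annotations on a common
reference sequence. Integrating such annotations is a client-side problem:
a genome browser has to pull feature sets from independent sources, keep
network traffic and memory in check while the user pans and zooms across
eight orders of magnitude (single bases to whole chromosomes), and draw
everything precisely positioned over the reference.

`dastrack` implements that computational core as a library plus a small CLI,
with no GUI attached: DAS 1.53 request construction and document parsing,
zoom-dependent payload reduction, an interval cache that never re-fetches a
base, deterministic glyph-based track rendering to SVG/PNG, flat-text session
persistence, and a deterministic synthetic DAS source (with a local HTTP
server) so everything runs and is testable offline. It is aimed at
bioinformaticians who want scripted, reproducible track images or a testbed
for DAS tooling.

## The model

**Zoom tiers.** The zoom measure is *bases per pixel*,
`b = span / pixel_width`. A viewport is rendered at one of three
granularities:

- `b <= 1/8` — **sequence** tier: at least 8 px per base, residues are drawn
  as letters;
- `1/8 < b <= T` — **individual** tier: one glyph per feature (default
  threshold `T = 1000` bp/px, configurable);
- `b > T` — **summary** tier: fixed-width bins, bin width snapped to the
  smallest power of 10 `>= b` so nearby zoom levels share cached payloads.

**Summary bins.** Bins tile the window from its start; per bin we keep the
overlap count (a feature counts once in every bin it overlaps, so long
features keep their visual mass), the fraction of bin bases covered by at
least one feature, and the maximum score. The invariant
`sum(count) = sum over features of #bins overlapped` is tested against a
brute-force oracle.

**Interval cache.** Payloads are cached per `(source, segment, tier)` as a
normalized interval set (sorted, disjoint, adjacent runs merged).
`plan_fetch()` splits a wanted range into covered and missing parts, so a
base fetched once is never fetched again; eviction is whole-entry LRU under
a byte budget (default 256 MiB) with optional TTL. Data is reduced to the
tier *before* caching — a summary window is stored as bins, not as the
features it came from.

**Rendering.** The pixel of base `p` in viewport `[s, e]` at width `W` is
`x = floor((p - s) * W / span)` — exactly invertible whenever
`span <= W`. Overlapping features are stacked by greedy first-fit bumping
with a configurable minimum pixel gap. Output is deterministic: SVG renders
are byte-identical and PNG renders pixel-identical across runs (the
rasterizer uses integer scanline fills and a built-in bitmap font — no
system fonts or graphics devices).

## Worked example

Everything below runs offline against the synthetic source:

```r
library(dastrack)

spec   <- mock_genome_spec(seed = 42)        # 2 chromosomes, 4 feature classes
genome <- generate_annotation_set(spec)
genome
#> <mock_genome> seed 42, 2 segment(s)
#>   chr1: 2e+06 bp, 4800 features
#>   chr2: 1e+06 bp, 4800 features

client <- das_client(transport = mock_transport(genome, "http://localhost/das/mock"),
                     verbose = TRUE)
src <- das_source_ref("http://localhost/das/mock")

info <- client_render(client, src, "chr1", 1, 250000, 1000, path = "region.svg")
#> [dastrack] tier for chr1:1-250000 at 1000 px: individual
#> [dastrack] http://localhost/das/mock chr1:1-250000 [individual]: 0 range(s) cached, 1 missing
#> [dastrack] fetched chr1:1-250000 (250000 bases)
#> [dastrack] rendered 3 track(s) to region.svg (250000 bases fetched)
info$tier
#> <zoom_tier> individual (250 bp/px)
```

At 250 bp/px the 250 kb window renders at the individual tier: one track per
type category (transcription, repeats, variants), 140 px tall including the
ruler. A second render of the same window is served entirely from the cache:

```r
info2 <- client_render(client, src, "chr1", 1, 250000, 1000, path = "region2.svg")
#> [dastrack] ... 1 range(s) cached, 0 missing
info2$fetched_bases
#> [1] 0
```

To go through real HTTP instead, serve the same genome locally and point any
command at it:

```sh
Rscript -e 'dastrack::das_serve(dastrack::mock_genome_spec(seed = 42), port = 8701)' &
Rscript inst/cli/dastrack render --url http://127.0.0.1:8701/das/mock \
    --segment chr1 --range 1,250000 --width 1000 --out region.svg
Rscript inst/cli/dastrack export-gff3 --url http://127.0.0.1:8701/das/mock \
    --segment chr1 --range 1,50000 --out region.gff3
```

CLI exit codes: `0` success, `1` usage error, `2` network failure, `3`
parse/format-version error, `4` timeout (retryable).

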