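Package: dastrack
Title: Headless Genomic DAS Client with Track Rendering and Caching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless client for the Distributed Annotation System (DAS)
    protocol. Builds DAS 1.53 requests, parses sources, entry point, sequence
    and feature documents into a tabular feature model, reduces feature
    payloads to a zoom-dependent granularity (individual features or fixed
    width summary bins), caches fetched intervals per (source, segment, tier)
    with LRU eviction and optional TTL expiry, lays out and renders multi-track
    genome views as deterministic SVG or PNG images from base level to whole
    chromosomes, and persists application state to flat-text session files.
    Ships a deterministic synthetic DAS source (generator, XML emitters and a
    local HTTP server) so the whole stack runs and is testable offline, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    S4Vectors,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    BiocGenerics,
    processx,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
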