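Package: hdflow
Title: Event-Driven Hyperdimensional Classification for Label-Free Flow
    Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying microparticles from event-based (dynamic
    vision sensor) recordings of optical interference patterns, as produced
    by label-free imaging flow cytometry. Provides an event-stream data
    model with plain-text and columnar-binary I/O, transit segmentation and
    polarity-aware frame accumulation, binary feature extraction with
    OR-pooling down-sampling, a hyperdimensional computing classifier
    (majority-vote prototype bundling and nearest-prototype Hamming
    classification), session-aware evaluation protocols that expose
    measurement bias (single-session versus intertwined splits), and a
    seeded optical/event-sensor simulator covering size-dependent
    diffraction patterns, ground-glass diffuser speckle broadening, and
    per-session acquisition drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
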