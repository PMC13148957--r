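Package: sramend
Title: Hybrid Reconstruction of Sequence Read Archive Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-run sample metadata for Sequence Read Archive
    (SRA) records by combining deterministic rule-based extraction with a
    pluggable language-model completion stage. Parses SRA run and BioSample
    XML, merges them with API field tables and user supplements, builds
    token-budgeted paragraph contexts, extracts values for 19 metadata
    classes with alias matching, a cell-line gazetteer, keyword heuristics
    and cross-source consistency checks, normalizes terms against disease
    and anatomy lexicons, routes the remaining classes to a backend behind a
    mockable contract with per-prediction perplexity confidence, and resolves
    rule and model values under configurable policies. Ships a synthetic
    benchmark generator with proximity-based in-distribution/out-of-
    distribution splits, leakage diagnostics, and an evaluation harness with
    context-tolerant matching, trivial baselines and an abstention versus
    substitution error taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
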