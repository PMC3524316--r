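Package: provdash
Title: Provenance-Aware Query Environment for Proteomics Experiment Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A provenance-aware query environment for proteomics and
    metabolomics experiment metadata. Provides a PROV-O-extending
    experiment-metadata ontology (classes, instance values, and typed
    instance-level relations) serialized as Turtle, a declarative mapping
    from ontology classes to columns of an experiment-metadata store, a
    boolean query-pattern engine with left-to-right connective folding,
    "smart filtering" of candidate facet values driven jointly by data
    co-occurrence and ontology instance-level relations, constraint
    propagation across query conditions, per-project result grouping, a
    saved-query catalog, and a seeded synthetic metadata generator that
    emulates affinity-purification mass-spectrometry (AP-MS) and shotgun
    expression proteomics records. A command-line interface exposes the
    full workflow for scripting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
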