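Package: cdrgraph
Title: Patient Health-Factor Graphs and Connection Delta Ratio Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-centered health-factor graphs from case/control
    electronic medical record (EMR) extracts, integrates them with a
    UMLS-style disease knowledge subgraph parsed from rich release format
    (RRF) files, and ranks every factor-value pair by the connection delta
    ratio CDR = (TPC - BPC) / (TPC + BPC), the relative strength of a
    factor's association with the target cohort. Includes a synthetic
    cohort and mock-ontology generator with known attachment probabilities
    so the whole pipeline is testable without access to hospital data or a
    licensed ontology release, graph queries over the labeled property
    graph, bulk-import/GraphML/query-script exporters, and a ranked
    health-factor distribution with cutoff and support filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
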