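Package: mirlink
Title: Joint Analysis of miRNA and mRNA Deregulation over Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative statistical analysis of deregulated microRNAs and
    deregulated mRNAs connected by a miRNA-to-target interaction table.
    Provides a chi-squared test of independence of deregulation status over
    interaction pairs (with a randomization control), hypergeometric
    over-representation analyses of three coordinated gene sets with an
    overlap-coding scheme, Venn overlap statistics, miRNA-family enrichment
    from miFam-style family files, and degree-constrained extraction of
    regulatory subnetworks with GraphML and SIF export. Includes a
    deterministic synthetic-data generator that emulates every input file
    dialect with planted statistical structure, and a pipeline driver that
    renders a plain-text analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
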