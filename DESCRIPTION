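Package: paredeg
Title: Degradome (PARE) Sequencing Analysis of Plant miRNA Cleavage Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying miRNA cleavage targets from
    degradome (PARE) sequencing libraries in plants. Covers raw-tag quality
    control and library accounting, priority-rule tag classification against
    tiered non-coding RNA references, plant miRNA:target duplex scoring with
    Allen-style position-weighted penalties, degradome-peak cleavage-site
    calling with the five-category peak classification and shuffle-based
    empirical p-values, two-condition target and network comparison (Venn
    counts and overlapped/independent decomposition), T-plot rendering, and
    2^-ddCt relative quantification for qRT-PCR follow-up. Includes a
    synthetic degradome simulator with planted, ground-truthed cleavage
    events so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
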