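Package: smallworldnet
Title: Small-World Analysis of Functional Brain Networks from ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for small-world analysis of functional connectivity
    networks built from regional BOLD time series: band-pass filtering and
    nuisance regression, Pearson correlation matrices with zeroed diagonal,
    absolute-value threshold binarization over a threshold grid, six binary
    graph indicators (clustering coefficient, average path length, global and
    local efficiency, node degree, at node and network level), degree-matched
    random-network null ensembles via Markov-chain double-edge swaps, the
    small-world indices gamma, lambda and sigma, and group-level comparison
    with Box-Cox normalization, two-sample t-tests and Bonferroni correction.
    Includes a synthetic generator of multi-subject, block-modular ROI time
    series so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2,
    optparse
Config/testthat/edition: 3
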