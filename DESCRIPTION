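Package: coexdiff
Title: Dual-Condition Signed Co-Expression Networks and Differential
    Correlation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks for two
    contrasted sample groups (for example salt-sensitive and salt-tolerant
    rice cultivars), selects the soft-threshold power by scale-free model
    fit, exports topological-overlap (TOM) thresholded networks, screens
    genes by degree/betweenness/closeness/clustering-coefficient
    centrality, detects gene pairs whose Pearson correlation changes
    between the groups with Fisher's z-test under FDR control, and reports
    transcription-factor-centred differential modules, GO term
    over-representation, and overlaps with marker (meta-QTL) intervals.
    Includes a two-group synthetic expression generator with planted
    modules, hubs and differential pairs so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
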