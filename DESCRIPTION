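Package: aggDE
Title: Aggregation, Exploration and Visualization of Multi-Contrast
    Differential Expression Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for combining per-contrast differential-expression
    result tables into a master gene-by-contrast result set by union or
    intersection of significant genes, filtering, sorting and subsetting
    the aggregate, and computing the numeric tables behind sixteen
    analytic visualizations (sample-distance heat maps, dendrograms, MDS
    with confidence ellipses or convex hulls, normalization box plots,
    fold-change distributions, divergence and up/down summaries, volcano
    plots, gene heat maps, expression profiles, Wilcoxon-annotated gene
    box plots, co-expression series and aggregation agreement densities).
    Includes trimmed-mean-of-M-values normalization, a minimal
    negative-binomial reference test, exact and approximate Wilcoxon
    rank-sum testing, Benjamini-Hochberg adjustment, a deterministic
    negative-binomial count simulator with planted differential
    expression, and a standardized project workspace with automatic
    figure and data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    ape,
    edgeR,
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
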