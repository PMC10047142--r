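Package: taxagree
Title: Hierarchy-Aware Inter-Annotator Agreement for Multi-Label Clinical Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring agreement between annotators who assign
    labels from a hierarchical labeling scheme to clinical free-text reports,
    such as chest X-ray reports. Builds virtual consensus annotators by
    k-of-n voting, computes per-label and micro-averaged Matthews correlation
    coefficients against a reference annotator, and quantifies partial
    (taxonomic) agreement by maximum-weight bipartite matching of label sets
    in which an exact label match outranks a match between an ancestor and a
    descendant, and cross-branch pairs are discarded. Includes label-usage
    accounting with Pareto coverage, a seeded generator of synthetic
    multi-annotator panels with controllable detection, specificity-drift and
    false-positive behavior, and a one-call pipeline that writes a full,
    reproducible analysis bundle.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
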