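Package: frapkin
Title: Quantification and Comparison of Fluorescence Recovery After
    Photobleaching (FRAP) Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying chromatin-binding kinetics from
    live-cell FRAP experiments on GFP-fusion proteins. Per-cell intensity
    traces (bleached region, whole nucleus, background) are normalized with
    correction for acquisition photobleaching, fitted with a constrained
    double-exponential association model, and summarized by the half-time of
    recovery obtained by bisection. Quality-control filtering on fitted
    plateau and adjusted R-squared, iterative Grubbs outlier elimination,
    one-way ANOVA with Tukey-Kramer multiple comparisons, and
    percent-of-control selectivity profiles reproduce the group-comparison
    workflow used in bromodomain-displacement assays. A seeded synthetic-data
    generator emulates both curve-level traces and image-level time-lapse
    stacks with known ground truth, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
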