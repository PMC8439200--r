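Package: synchrometab
Title: Dose-Response Metabolic Network Analysis via Entropy, Yin-Yang
    Transformation Patterns and Synchronous Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses targeted-metabolomics dose-response studies as weighted
    correlation networks. Builds per-group soft-thresholded correlation
    networks with scale-free topology selection and computes degree-based
    network structure entropy; classifies each metabolite's two-stage
    expression change into six Yin/Yang transformation patterns and tracks
    their dose trends; estimates Kendall tau-a rank-correlation networks with
    synchronous/anti-synchronous edge classes; detects densely connected
    modules with an MCODE implementation; compares modules across dose
    conditions (full-course, partial, conservative-allosteric, emerging);
    and runs hypergeometric over-representation analysis against
    user-supplied pathway sets. Includes a synthetic-study generator with
    planted pattern labels and planted correlated modules so every stage has
    recoverable ground truth.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
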