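Package: tmrnet
Title: Treatment-Measured-Response Integration of Multi-Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates treatment, multi-omics and physiological response
    tables from a common set of samples into covariate-adjusted association
    networks. Provides compositional handling of 16S taxa tables (relative
    abundance, top-n pooling, additive log-ratio transform), Shapiro-Wilk
    guided variable transforms with PCA-based proxy-variable selection,
    three categories of covariate-adjusted linear association models with
    bidirectional resolution and signed network construction, Mantel-statistic
    inter-group dendrograms with Ward clustering, classical multidimensional
    scaling and a permutation-based PERMANOVA, plus a synthetic
    microbiome-metabolome-physiology study generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
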