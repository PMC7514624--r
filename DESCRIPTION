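Package: nrhreduct
Title: Neighborhood Rough-Set Attribute Reduction with Roughness Joint Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attribute reduction (feature selection) for continuous-valued
    decision tables using neighborhood rough sets under a counting-measure
    specialization of the Lebesgue measure. Implements neighborhood classes,
    lower and upper approximations with precision and roughness, the
    neighborhood roughness joint entropy (NRH) uncertainty measure combining
    the algebra and information views, internal and external attribute
    significances, and a core-plus-greedy heuristic reduction algorithm
    (ARNRJE) with a completeness pruning pass. Includes Fisher-score
    prefiltering for high-dimensional gene-expression-style tables, a
    stratified cross-validation harness (3-NN and linear SVM), a synthetic
    decision-table generator, delta-sweep utilities with ggplot2 graphics,
    and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
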