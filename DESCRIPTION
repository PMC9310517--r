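Package: hierclass
Title: Hierarchical Classification Approaches, Metrics and Guidelines for
    Tree-Structured Biological Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying instances into tree-structured class
    hierarchies such as CATH structural codes or Enzyme Commission numbers.
    Implements the Global (flat over full label paths), Local-per-Level and
    Local-per-Node (top-down) approaches over an injected flat base learner;
    hierarchical precision, recall and F-measure over ancestor-augmented
    label sets; dataset characterisation by per-level class-size statistics
    and the Variation coefficient; a preparation pipeline with minimum-class
    filtering and NearMiss semi-balancing; a stratified cross-validation
    harness with paired comparisons; a rule-based engine that recommends an
    approach from dataset properties; and a synthetic generator for
    hierarchical Gaussian datasets with controllable imbalance and
    partial-depth labelling.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    pROC,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
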