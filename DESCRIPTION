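Package: etpfam
Title: Ensembles of Windowed Deep Classifiers for Protein Family Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates protein sequences with domain families by sliding a
    small residual convolutional classifier over per-residue embedding tracks
    and combining several such base models with classical and learned voting
    schemes. Per-window class scores are collapsed into one score vector per
    sequence by the central-window, sliding-window-area or
    sliding-window-coverage rule; base models are then ensembled by simple or
    score voting, per-model learned weights, per-family learned weights
    (perceptron or MLP head) or stacking, with combiner weights fitted by
    gradient descent on a development partition. Includes dataset-hygiene
    filters (length cutoff, cross-partition deduplication), a deterministic
    synthetic embedder and benchmark generator so the whole pipeline runs at
    desk scale, per-family error and F1 reporting, rescue analysis, and
    performance binned by family size or test-to-train similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
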