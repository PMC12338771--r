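Package: coexist
Title: Single-Cell Integration of Serial Multiplexed Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches the same physical cells across consecutive multiplexed
    tissue image (MTI) sections by combining segmentation-mask overlap with
    Spearman correlation of shared markers. Provides a Monte Carlo simulator
    for the expected fraction of nuclei shared between sections, an
    overlap-majority cell tracker with cycle consistency, a spatially
    constrained rectangular linear sum assignment matcher, the combined
    overlap-plus-correlation matcher, k-nearest-neighbour propagation of
    combined-panel cell-type labels, recurrent cellular neighbourhood
    analysis, evaluation metrics, and a synthetic serial-section generator
    with ground-truth cross-section pairings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
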