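Package: pfascat
Title: Hierarchical Structural Categorization of Per- and Polyfluoroalkyl
    Substances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hierarchical structural categories for per- and
    polyfluoroalkyl substances (PFAS) from SMILES input: structure
    standardization and InChIKey deduplication, a three-pattern structural
    PFAS definition filter, degradation-product merging, primary class
    assignment with a membership-driven hybrid rule, perfluorinated
    chain-length binning, circular-fingerprint Jaccard clustering to terminal
    categories under an objective distance threshold, centroid and MaxMin
    representative selection with diversity-coverage curves, exposure and
    physicochemical annotation with a candidate-triage workflow, in vivo
    point-of-departure harmonization to human-equivalent benchmark doses,
    structural-feature enrichment against assay-derived flags by Fisher's
    exact test, and a random-forest classifier that assigns new substances to
    terminal categories. Includes deterministic synthetic-landscape
    generators so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
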