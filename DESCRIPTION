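Package: bkassay
Title: Quantification, Rank Scoring and Comparative Inference for Bacterial Killing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for serial-dilution bacterial killing assays (BKA) read on
    96-well plates at two timepoints. Computes background-drift-corrected
    killing capacities from plate-reader absorbance tables, classifies
    per-dilution capacities and assigns half-integer endpoint ranks on the
    0-8 scale, and runs the nonparametric comparative inference used in
    eco-immunology: Kruskal-Wallis with Dwass-Steel-Critchlow-Fligner
    posthoc comparisons, Jonckheere-Terpstra and Skillings-Mack permutation
    tests, Fisher's exact test for r x c tables, and Mantel comparison of a
    species-level killing-profile distance matrix against a phylogenetic
    distance matrix, with centroid-linkage clustering and Newick export.
    Includes a seeded synthetic plate-data generator emulating the
    threshold-type killing behaviour of carnivore serum so the full pipeline
    is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
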