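Package: rerscan
Title: Relative Evolutionary Rate Scans for Trait-Associated Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose evolutionary rate shifted on phylogenetic
    branches associated with a phenotype. Branch lengths from per-gene trees
    are regressed on consensus branch lengths after a variance-stabilizing
    transform; the residuals (relative evolutionary rates, RERs) are tested
    for association with binary foreground/background branch designs (Kendall
    rank correlation, with Fitch maximum-parsimony ancestral reconstruction
    of the trait) or with continuous species traits (Pearson correlation).
    Per-gene results feed signed foreground acceleration scores into
    rank-based gene-set enrichment with Jaccard clustering of enriched
    pathways. A fully seeded synthetic-data generator produces master trees,
    gene trees with planted rate shifts, traits and gene sets with known
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
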