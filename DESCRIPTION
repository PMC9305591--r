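Package: temporalfst
Title: Temporal F_ST Outlier Scans for Parallel and Divergent Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects SNPs under putative selection by contrasting
    contemporary native, contemporary invasive, and historical (museum)
    population samples. Implements per-site and sliding-window
    Weir-Cockerham F_ST, top-percentile window selection with a
    ranked-value knee threshold, pooling with external (BayeScan-style)
    outlier calls, and classification of outliers into divergent,
    parallel, and single-comparison categories. Includes chromosome-class
    enrichment tests with Pearson residuals, inbreeding-coefficient
    bioinformatic sexing, a major-allele-frequency interaction ANOVA,
    population-structure summaries (pairwise F_ST, Nei's distance,
    neighbour-joining tree, PCA), and a forward Wright-Fisher simulator
    of an invasion with temporal sampling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
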