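Package: crosswiser
Title: Crosswise Permutation Tests for the Association of Multiple Genomic Region Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the pairwise association between many genomic region
    sets simultaneously using permutation tests with pluggable randomization
    and evaluation functions.  Z-scores are normalized by the square root of
    the number of permuted regions so that tests of different sizes are
    directly comparable.  A single randomization pass per query set is reused
    against every target set, making all-against-all testing tractable.  The
    resulting association matrix can be thresholded on adjusted p-values,
    clustered with an automatically selected hierarchical linkage, projected
    with PCA, t-SNE or UMAP, and each association dissected positionally with
    local (shifted) Z-score profiles.  Ships a synthetic four-chromosome
    "alien genome" generator with region-set families of graded similarity,
    composite, flanking and negative-control sets, so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
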