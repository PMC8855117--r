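Package: astromorph
Title: Astrocyte Morphotype Discovery and Microsatellite Association for
    Migratory Shorebirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the three-dimensional morphology of
    hippocampal astrocytes to migratory phenotype in shorebirds.  Reads
    digital cell reconstructions (SWC), applies z-axis shrinkage
    correction and stereological probe-grid sampling, computes a panel of
    19 morphometric variables including a composite branching-complexity
    score, screens features with a bimodality coefficient, discovers
    morphotypes by Ward minimum-variance clustering with canonical
    discriminant validation, and runs permutation inference (PERMANOVA,
    PERMDISP, pairwise pseudo-t) on Euclidean distance matrices.  A
    companion population-genetics module computes microsatellite
    diversity (A, Ho, He), Hardy-Weinberg tests, FST/RST differentiation,
    and the association of allele size with migratory distance.  A
    stochastic branching simulator generates labelled synthetic
    populations so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    digest,
    pracma,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    e1071,
    withr
Config/testthat/edition: 3
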