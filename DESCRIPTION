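Package: coldtol
Title: Cold-Tolerance Scoring and Gene-Family Expression Analytics for Potato
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the quantitative pipeline
    used in gene-family cold-tolerance studies of tetraploid potato: a
    membership-function/PCA comprehensive cold-tolerance score (D value) with
    threshold classification and clustering, the tau tissue-specificity
    index, a log2 fold-change/FDR cold-induction screen, 2^-ddCt qPCR
    relative quantification with Kruskal-Wallis/Dunn letters, IUPAC
    cis-element promoter scanning with five-class summaries, and
    Nei-Gojobori (1986) Ka/Ks estimation with tandem/collinear duplication
    classification. Every stage is paired with a seeded synthetic-data
    generator that embeds known ground truth, so the whole pipeline is
    testable without the original study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    Biostrings,
    yaml,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
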