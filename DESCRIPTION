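Package: cernascreen
Title: Consensus Screening of ceRNA (lncRNA-miRNA-mRNA) Axes from
    Multi-Dataset Expression Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate tumor-suppressor and oncogene
    long non-coding RNAs (lncRNAs) from heterogeneous collections of
    expression datasets and for reconstructing lncRNA-miRNA-mRNA
    ("competing endogenous RNA") axes. Implements per-dataset differential
    screening of protein-coding "bait" genes against clinical severity
    contrasts with cross-dataset consensus voting, Pearson correlation
    screens with false-discovery-rate control, evidence-table merging for
    miRNA binding and validated targets, sign-constrained triplet assembly,
    and 2^-ddCt relative quantification statistics for qPCR validation.
    Includes a seeded synthetic-cohort generator with planted ground truth
    so every stage can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
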