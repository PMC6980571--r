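Package: panelcompare
Title: Concordance Evaluation of Targeted Myeloid NGS Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate and compare targeted next-generation sequencing
    gene panels for myeloid malignancies. Models panel target designs (BED) and
    gene-level clinical relevance; summarizes per-gene sequencing depth and
    limits of detection; normalizes, keys and filters variant calls (VCF);
    builds a four-state call matrix (called / not called / not included /
    not done) across panels to count concordant and discordant clinically
    relevant variants; analyzes indel-length missingness and cross-panel
    variant-allele-frequency concordance; detects recurrent low-VAF sequencing
    artifacts in homopolymer and triplet-repeat context; and generates fully
    specified synthetic cohorts with provenance bookkeeping for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    withr,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
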