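Package: hybridscar
Title: Genomic Instability Analysis for F2 Inter-Strain Mouse Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genomic instability in F2 embryos from
    crosses of two inbred mouse strains using whole-exome allele depths.
    Includes a synthetic F2-cross simulator (recombinant ancestry mosaics,
    copy-neutral LOH, deletions and aneuploidies, binomial read sampling),
    variant-allele-fraction based triage of germline versus somatic
    variants, strain-origin segmentation of the genome with allelic
    imbalance scoring, a panel-of-normals copy-ratio workflow with
    changepoint segmentation, and organism-level statistics: exact
    binomial tests of Mendelian segregation with Bonferroni correction
    and Clopper-Pearson intervals, multinomial goodness of fit for
    two-locus litters, and single-hit limiting-dilution estimation of
    repopulating-cell frequency with likelihood-ratio comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
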