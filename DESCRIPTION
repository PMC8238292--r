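Package: neoclone
Title: Subclonal Dynamics and Copy-Number Loss Prioritization Under
    Neoadjuvant Androgen Deprivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links subclonal somatic copy-number loss to response to
    neoadjuvant androgen-deprivation therapy in longitudinal tumor
    samples. Provides cancer-cell-fraction estimation from variant allele
    frequencies under purity and local copy number, binomial-mixture
    clustering of clonal populations with longitudinal matching,
    subclonality classification of copy-number segments with a
    low-fraction rescue rule, a paired test for FFPE deamination
    artifacts, overlap-plus-expression candidate-gene prioritization,
    per-cell FISH prevalence quantification with response correlation,
    the exact Simon two-stage phase II design search, and a synthetic
    longitudinal cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
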