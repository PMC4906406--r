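Package: ctdnaprof
Title: Resistance Profiling of EGFR-Mutant Lung Cancer from Circulating
    Tumour DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling drug-resistance mechanisms in non-small
    cell lung cancer from targeted deep sequencing of plasma cell-free
    DNA. Implements gene-level somatic copy-number detection from capture
    depth via a calibrated z-score copy-number index, circulating tumour
    DNA fraction estimation from truncal or copy-number-corrected driver
    variant allele frequencies, the T790M-to-activating-mutation clonal
    ratio with limit-of-detection censoring, rule-based calling of
    emergent and increasing resistance alterations with innate versus
    acquired classification (including the Freeman-Halton exact test for
    r x c contingency tables), and an in-silico spike-in framework for
    benchmarking copy-number detection sensitivity and specificity.
    Includes a synthetic-cohort generator so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    IRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
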