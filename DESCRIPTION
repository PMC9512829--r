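Package: hrdkit
Title: Homologous Recombination Deficiency Calling and Assay Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for calling homologous recombination deficiency (HRD) in
    tumor samples by three complementary routes: genomic-scar scoring
    (loss of heterozygosity, telomeric allelic imbalance and large-scale
    state transitions from allele-specific copy-number segments), shallow
    whole-genome copy-number segmentation with large-scale genomic
    alteration counting across a ladder of window sizes, and functional
    RAD51-foci immunofluorescence scoring with quality-control gates.
    Includes diagnostic-concordance statistics (Cohen's kappa with exact
    Clopper-Pearson intervals, sensitivity and specificity, kappa-precision
    sample-size planning), survival analysis of biomarker strata, and a
    synthetic-data generator that produces every input format with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
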