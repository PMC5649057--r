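Package: lumoscall
Title: Tumor-Only Somatic Variant Calling via Allelic Copy Number and Clonal
    Sample Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A Bayesian framework for calling somatic variants in unmatched
    (tumor-only) sequencing. Position reliability scores are learned from a
    panel of unmatched controls, candidate sites are quality-filtered with a
    semi-supervised quadratic discriminant model, allele-specific copy number
    and clonal sample fractions are fit by expectation-maximization over
    segmented depth ratios and beta-binomial allele fractions, and each
    candidate site receives posterior probabilities of being somatic, germline
    heterozygous, germline homozygous, or other. Includes a coverage/tumor
    fraction power simulator and a synthetic cohort generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
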