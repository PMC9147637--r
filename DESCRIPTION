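Package: easa96
Title: Analysis Pipeline for the 96-Well Electrophilic Allergen Screening Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Complete data-analysis system for a 96-well in chemico skin
    sensitization screen based on depletion of two electrophile-reactive
    probe molecules (4-nitrobenzenethiol, read by absorbance at 412 nm, and
    pyridoxylamine, read by absorbance at 324 nm and fluorescence at
    ex 324/em 398 nm). Covers the fixed plate layout with in-process
    controls, plate-reader CSV ingestion, probe-depletion statistics with
    Welch-Satterthwaite inference, a Gibbs-sampler Bayesian classifier, a
    k-times-SD rule, bubble/interference/pipetting quality control with
    3-SD control charting, Z-factor and positive-control IC50 assay-quality
    metrics, defined-approach integration ("2 out of 3" and KE 3/1) with
    Cooper concordance statistics against in vivo reference calls, and a
    synthetic plate generator that stands in for the laboratory instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
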