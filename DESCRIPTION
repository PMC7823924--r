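Package: bidirMR
Title: Bi-Directional Two-Sample Mendelian Randomization with Pleiotropy
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for bi-directional two-sample Mendelian randomization
    (MR) of a continuous biomarker and a binary disease trait, motivated
    by the serum 25-hydroxyvitamin D / depression question. Provides GWAS
    summary-statistic reading, quality filtering and allele harmonization;
    the inverse-variance-weighted, MR-Egger, weighted-median and
    weighted-mode causal estimators; the MR-PRESSO global, outlier and
    distortion resampling tests; leave-one-out and single-variant
    diagnostics; fixed-effect meta-analysis across outcome cohorts;
    effect-scale conversions (odds ratio per 50% higher exposure, percent
    change in the outcome) and a binary-outcome power calculation; a
    tiered-adjustment observational arm with trend, curvature and
    interaction tests; and a synthetic two-sample GWAS generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
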