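Package: tiradsx
Title: TI-RADS Risk Stratification of Thyroid Nodules with Elastography and 4D Doppler
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based risk stratification of thyroid nodules under five
    Thyroid Imaging Reporting and Data Systems (EU-TIRADS, ACR TI-RADS,
    Horvath TI-RADS, French TI-RADS, and a French variant augmented with
    strain elastography and volumetric 4D Color Doppler suspicion features),
    together with diagnostic-performance evaluation against a pathology gold
    standard (per-category contingency tables, calculated malignancy risk,
    sensitivity, specificity, predictive values, accuracy), a calibrated
    synthetic cohort generator for testing the pipeline without patient
    data, and a binomial logistic generalized linear model fitted by Fisher
    scoring with deviance, AIC and Wald inference for predictor analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
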