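Package: xradi
Title: Image-Augmented Deterioration Indices for Hospitalized Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments electronic-health-record deterioration indices with
    chest-radiograph-derived risk scores. Provides a synthetic cohort
    simulator with a shared latent severity observed through both an index
    stream and image scores, temporal alignment of irregular score streams
    onto a 4-hour prediction grid with carry-forward imaging features, a
    small feed-forward fusion network over the four-element feature vector
    (image score, index score, hours since radiograph, hours since
    admission), and patient-level evaluation: negative-predictive-value
    sweeps for low-risk identification and AUROC with bootstrap confidence
    intervals for high-risk discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
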