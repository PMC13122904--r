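Package: ubrmonitor
Title: Bayesian Prediction and Monitoring of Trial Accrual and
    Underrepresented-Group Enrollment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interim monitoring of clinical-trial recruitment. Models
    enrollment waiting times as exponential with a conjugate inverse-gamma
    prior on the mean waiting time, and membership in each
    underrepresented-in-biomedical-research (UBR) category as binomial with a
    conjugate beta prior. Couples the two posterior predictive distributions
    by simulation to forecast, at any interim look, the final sample size and
    the combined rate of UBR enrollment (rUBR), with credible intervals and
    probabilities of meeting study targets. Includes a synthetic-trial
    generator, readers for subject-level enrollment logs and aggregated
    interim summaries, JSON reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
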