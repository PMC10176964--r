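Package: recurtte
Title: Parametric Time-to-Event Modelling of Recurrent Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric time-to-event analysis of recurrent ischemic stroke
    after an index stroke. Implements piecewise baseline hazards (constant,
    Gompertz, Weibull), proportional-hazards covariate effects, an optional
    log-normal frailty integrated by Laplace approximation, exact-event-time
    maximum likelihood with objective-function-value (OFV) model comparison,
    stepwise covariate model building with likelihood-ratio thresholds,
    Kaplan-Meier visual predictive checks, and sampling importance resampling
    for parameter uncertainty. Includes a synthetic registry-cohort generator
    with inverse-cumulative-hazard event simulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pracma,
    withr
Config/testthat/edition: 3
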