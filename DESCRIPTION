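Package: respcomp
Title: Simulation and Dosimetric Evaluation of Couch-Based Respiratory Motion Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for evaluating a couch-mounted respiratory
    compensating system. Generates sinusoidal and irregular breathing
    displacement traces and strain-gauge surrogate voltages, calibrates the
    surrogate against target motion with a similar-triangle fluoroscopy
    projection model, simulates latency-limited reverse-motion couch
    compensation, accumulates motion-blurred dose on a virtual radiochromic
    film from an error-function beam model, and computes the kinematic and
    dosimetric endpoints of such an evaluation: per-cycle compensation rates,
    position and compensating errors, 95%/5% isodose areas, in-field mean
    dose, and the global 3%/3mm gamma passing rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
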