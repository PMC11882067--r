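Package: lcscreen
Title: Cost-Effectiveness Model for Volume-Based Low-Dose CT Lung Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision tree feeding a three-state Markov cohort model to
    evaluate annual lung cancer screening with volume-based low-dose computed
    tomography against no screening in a high-risk population, from a
    healthcare payer perspective. Screening-round outcomes follow the NELSON
    trial; long-term survival per stage is built by reconstructing
    individual-patient data from digitised Kaplan-Meier curves, fitting
    parametric families, and extrapolating under a background-mortality floor.
    Includes deterministic (one-way) and probabilistic sensitivity analyses
    with Dirichlet/Beta/Gamma parameter distributions, cost-effectiveness
    acceptability curves, and a declarative scenario grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
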