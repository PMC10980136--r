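Package: antimiRsim
Title: Translational Pharmacokinetic-Pharmacodynamic Simulation of
    Nanoparticle-Delivered Anti-miR-155 Therapy in NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale ordinary-differential-equation model of tumor
    response to systemically administered, nanoparticle-delivered
    anti-miR-155 in non-small-cell lung cancer, alone or combined with
    cisplatin and immune checkpoint inhibitors (atezolizumab,
    pembrolizumab). Provides pooled nonlinear least-squares calibration
    against multi-arm tumor growth data, allometric mouse-to-human
    scaling, local and global (Latin hypercube, regression-based)
    sensitivity analysis, Hill dose-response characterization with EC_p
    inversion, virtual patient cohort generation with RECIST 1.1
    response evaluation, Kaplan-Meier progression-free survival and Cox
    hazard ratios, and Chou-Talalay median-effect synergy screening of
    two- and three-drug combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    survival,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
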