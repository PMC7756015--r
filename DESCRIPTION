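Package: coaflow
Title: Reduced-Order Hemodynamics and Non-Invasive Diagnosis of Aortic
    Coarctation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the non-invasive assessment of aortic coarctation
    (CoA) from vascular geometry alone.  A reduced-order aortic-arch
    network is solved for steady flow under single-resistance lumped
    parameter outlet boundary conditions, the outlet resistances are swept
    through six levels to trace the stenosis pressure-flow curve
    dp = f*Q + s*Q^2, and the fitted viscous friction f and expansion
    loss s feed a logistic diagnostic model whose performance is
    evaluated by stratified 5-fold cross-validation (ROC/AUC with DeLong
    inference) against a catheterization-style peak systolic pressure
    gradient reference and the ESC anatomic narrowing-rate criterion.
    Includes a calibrated virtual pediatric cohort generator for
    end-to-end experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
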