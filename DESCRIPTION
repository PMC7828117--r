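Package: nanomsc
Title: Mechanism-Based PK-PD Modeling of Nano-Engineered Mesenchymal Stem
    Cell Drug Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a mechanism-based pharmacokinetic-pharmacodynamic
    (PK-PD) analysis of paclitaxel delivery by nano-engineered mesenchymal
    stem cells (nano-MSCs) in an orthotopic mouse lung-tumor model. The
    drug is tracked in three parallel compartmental layers (free drug,
    PLGA-nanoparticle-bound, and MSC-associated), each with central,
    peripheral and tumor compartments; tumor uptake follows parallel
    vascular-exchange and surface-exchange (Krogh-cylinder type)
    processes. The package provides the coupled tumor-growth model with
    saturable and linear kill terms, first-order in-vitro release and
    exocytosis fits, a bioluminescence-to-volume power calibration,
    naive-pooled maximum-likelihood PK estimation fitted layer by layer,
    Laplacian mixed-effects PD estimation with modified-M3 dropout
    censoring, sampling-importance-resampling confidence intervals,
    prediction-corrected visual predictive checks, dosing-regimen
    simulation studies, and synthetic-study generators that emulate the
    original destructive-sampling PK and bioluminescence PD designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    minpack.lm,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
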