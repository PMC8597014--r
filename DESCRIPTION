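Package: acmig
Title: Kinetics of Acetyl Group Migration and Hydrolysis in Mannan
    Oligo- and Polysaccharides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting of first-order reaction networks
    describing base-catalysed acetyl group migration (O2/O3 exchange and
    O2-to-O6 transfer across the glycosidic bond) and ester hydrolysis in
    beta-(1->4)-linked mannan model trisaccharides and in
    galactoglucomannan polysaccharide. Provides pH-corrected
    pseudo-first-order rate matrices, stiff (BDF) and exact
    matrix-exponential forward simulation, ODE-constrained nonlinear
    least-squares estimation of the tied rate constants (Nelder-Mead
    simplex followed by Levenberg-Marquardt) with linearized standard
    errors and a degree-of-explanation statistic, a synthetic
    NMR-time-course generator with pH-drift and noise models for
    parameter-recovery studies, and CSV readers and writers for
    time-course, pH-log and acetyl-peak-integral tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
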