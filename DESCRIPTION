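Package: occuPET
Title: Compartmental Kinetics, Graphical Analysis, and Receptor Occupancy
    for Dynamic PET
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of dynamic small-animal PET studies of receptor
    occupancy. Implements one- and two-tissue reversible compartment models
    with a fractional blood-volume term, weighted nonlinear least-squares
    fitting with AIC model selection, Logan and Patlak graphical analysis,
    population-based parent-fraction (metabolite) correction of arterial
    plasma input functions, bi-exponential tissue clearance fitting,
    receptor-occupancy computation from distribution volumes or binding
    potentials, non-displaceable volume (V_ND) extrapolation across drug
    doses, and in vivo ED50 estimation by Hill/Emax regression. Includes a
    synthetic-study generator with known ground truth that emulates a
    21-frame, 65-minute rodent acquisition with arterial sampling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, minpack.lm, yaml
Suggests: deSolve, jsonlite, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
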