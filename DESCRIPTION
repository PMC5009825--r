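Package: leukodyn
Title: Compartmental Modeling of Hematopoietic and Leukemic Cell Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and fitting three-compartment
    (peripheral blood, spleen, bone marrow) ordinary-differential-equation
    models of normal and leukemic hematopoietic cell kinetics, including
    nested stem/progenitor (HSC/HPC) and quiescence (G0) sub-models.
    Provides a catalogue of elementary kinetic rate laws with Hill-type
    leukemic-influence modifiers, enumeration of candidate model structures,
    genetic-algorithm parameter estimation with bounded least-squares
    refinement against a root-mean-square-deviation criterion (d <= s),
    mechanistic rate decomposition along fitted trajectories, interval
    differentiation-flux analysis, one-tailed t-test model selection
    (cell mobility, G0 re-entry), and a synthetic-data generator emulating
    experimental leukemia time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
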