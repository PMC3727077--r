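Package: vegftrap
Title: Three-Compartment Model of VEGF Transport, Kinetics and Anti-VEGF
    Dosing in Tumor-Bearing Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body compartment model of vascular endothelial growth
    factor (VEGF) transport and kinetics in mice bearing human tumor
    xenografts.  The model comprises three well-mixed compartments (normal
    tissue, blood, tumor) exchanging molecular species via microvascular
    permeability and lymphatic drainage, a rule-based mass-action reaction
    network covering mouse (VEGF120/164) and human (VEGF121/165) isoforms,
    receptors (VEGFR1, VEGFR2), neuropilin co-receptors (NRP1, NRP2),
    matrix glycosaminoglycan sites, soluble VEGFR1, alpha-2-macroglobulin,
    and the decoy receptor VEGF Trap (aflibercept).  Provides derivation of
    tumor-compartment geometry from primitive measurements, stiff ODE
    simulation of intravenous dosing schedules with exponential tumor
    growth, bounded multi-start weighted nonlinear least-squares parameter
    estimation, extended Fourier Amplitude Sensitivity Test (eFAST) global
    sensitivity analysis, synthetic plasma time-course generation, and
    SBML export of the assembled network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
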