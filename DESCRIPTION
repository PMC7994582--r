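Package: ctdbind
Title: Quantitative Analysis of Prolyl Isomerase Binding to Phospho-CTD Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fitting and simulation tools for the solution binding assays used
    to characterise bivalent interactions between parvulin-class prolyl
    isomerases (Ess1/Pin1) and phosphorylated heptad-repeat peptides from the
    RNA polymerase II carboxy-terminal domain (CTD). Provides a parser for the
    heptad-repeat peptide notation; closed-form and bracketed-root solvers for
    single-site, two-site and competitive binding equilibria; signal-weighted
    sedimentation-coefficient (sw) isotherm prediction and constrained
    least-squares fitting for sedimentation-velocity analytical
    ultracentrifugation; per-residue NMR chemical-shift-perturbation titration
    Kd fitting with ligand depletion and threshold-based aggregation;
    four-parameter-logistic competition anisotropy IC50 fitting; Guinier
    analysis of small-angle scattering profiles with the qRg < 1.3 window rule
    and extrapolation of Rg to infinite dilution; and seeded synthetic-data
    generators for every assay so each fitting stage can be exercised by
    parameter-recovery simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
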