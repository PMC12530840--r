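Package: protonbind
Title: Binding Equilibria, ITC Modelling and Protonation-State Analysis for
    Protein-Fragment Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational chain for deciding whether a weakly binding,
    titratable fragment engages a kinase ATP site in its neutral (protonated)
    form. Provides closed-form and numerical solvers for single-site and
    competitive binding equilibria together with the isothermal titration
    calorimetry (ITC) design formulas (Wiseman c value, required fragment
    concentration for a target saturation, displacement-titration inversion of
    the apparent affinity); simulation and one-site fitting of integrated-heat
    thermograms for direct and displacement titrations; Henderson-Hasselbalch
    protonation arithmetic, sigmoid pKa fitting from titration curves and the
    thermodynamic linkage between a binding-induced pKa shift and the free
    energy preference for the protonated ligand; and hydrogen-bond occupancy
    and persistence analysis of donor-acceptor distance series extracted from
    molecular dynamics trajectories. Seeded synthetic-data generators emulate
    every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
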