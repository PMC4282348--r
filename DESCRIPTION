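Package: refassess
Title: Assessment of Protein Model Refinement Predictions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to score and rank protein structure refinement
    predictions against a native target and a released starting model,
    in the style of a CASP refinement-category assessment.  Implements
    the high-accuracy Global Distance Test (GDT-HA) with a multi-seed
    superposition search, Calpha RMSD after optimal superposition,
    side-chain GDC-SC, the SphereGrinder local-environment score,
    per-target robust Z-score ranking with clipping and a combined
    S_p score, a naive (resubmitted starting model) baseline,
    one-tailed Wilcoxon signed-rank head-to-head comparisons,
    geometric hydrogen-bond network scoring by precision/recall/F1,
    a Hookean elastic-network deformation energy for thermal-ensemble
    filtering and adventurousness analysis, molecular-replacement
    viability summaries from externally supplied LLG scores, and a
    seeded synthetic-round generator with planted per-group skill for
    end-to-end validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
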