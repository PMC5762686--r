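Package: screenval
Title: Hit-Validation Analytics for Ensemble Structure-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis stack for validating hits from
    ensemble-based structure-based virtual screening against the Hsp90
    N-terminal ATP-binding domain and similar targets. Implements ROC-based
    enrichment metrics (AUC, log-scaled AUC emphasising early enrichment,
    enrichment factor at 1% false-positive rate), docking-pose reproduction
    judging by heavy-atom RMSD, hydrogen-bond occupancy from distance time
    series, NMR chemical-shift-perturbation quantification and residue
    classification, two-site-exchange line-shape simulation and dissociation
    constant fitting for slow-exchange titrations, melting-temperature
    extraction from differential scanning fluorimetry curves, and
    fingerprint-based chemical-novelty analytics (Tanimoto, summed Tc,
    ligand efficiency, Lipinski curation). Synthetic-data generators with
    known ground truth stand in for docking engines, spectrometers and
    compound libraries so every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    withr,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
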