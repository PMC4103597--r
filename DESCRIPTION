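Package: memqa
Title: Membrane-Protein Model Quality Assessment with Side-Chain Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-model quality assessment for membrane-protein structural
    models. Scores all-atom models with a trainable linear per-residue quality
    predictor combining sequence-profile features with structural features
    (solvent accessible surface area, hydrogen-bond secondary structure,
    atom-atom and residue-residue contacts, membrane depth), and boosts model
    selection by fixed-backbone side-chain resampling: each model is repacked
    against a backbone-dependent rotamer library several times, every repacked
    decoy is rescored, and models are ranked by their best resampled score.
    Includes the full evaluation layer (TM-score, per-target Z-scores,
    chi1/chi2 side-chain correctness) and a synthetic helix-bundle decoy
    benchmark so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
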