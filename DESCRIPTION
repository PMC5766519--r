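Package: h12assay
Title: Helix-12 Activation Assay for Nuclear-Receptor Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory-based classification of the estrogen receptor alpha
    ligand-binding domain as agonist-like (active) or antagonist-like
    (inactive). Implements region-aggregated dynamic cross-correlation
    scoring with a +/-0.6 coefficient threshold, the per-residue helix-12
    correlation profile and its score-4 activation rule, geometric
    hydrogen-bond / salt-bridge / hydrophobic-contact / pi-stacking
    persistence analysis, GROMOS (Daura) RMSD clustering, Kabsch
    superposition with RMSD/RMSF, an alpha-helix i->i+4 hydrogen-bond
    helicity tracker, and a seeded synthetic dimer-trajectory generator
    with planted covariance, occupancy, conformer-mixture and helicity
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
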