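Package: dimerfit
Title: Competitive Dimerisation Equilibria, Interface Contacts and
    Differential HDX for Chaperone-Client Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of competitive homo- and
    hetero-dimerisation equilibria measured by native mass spectrometry:
    a coupled-equilibrium forward model, dissociation-constant fitting
    with replicate and bootstrap uncertainties, and conversion of KDs
    into binding free-energy ledgers with propagated errors. Also
    provides hydrogen-bond occupancy and difference maps and per-residue
    interface contact profiles from multi-model PDB trajectories,
    superposition RMSD, charge-state bookkeeping for native MS peak
    lists, differential hydrogen-deuterium exchange (HDX-MS) statistics
    with Woods-plot exports, and seeded synthetic-data generators with
    ground-truth sidecars for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
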