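Package: premap
Title: Paramagnetic Relaxation Enhancement Mapping and Docking Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies paramagnetic relaxation enhancements (PREs) from NMR
    peak intensities measured on spin-labelled protein complexes, converts
    them into electron-nucleus distance restraints via the
    Solomon-Bloembergen model-free formalism, maps binding interfaces from
    chemical shift perturbations (CSPs) with active/passive residue
    classification, and assembles, filters and exports ambiguous interaction
    and distance restraints for data-driven docking. Includes a synthetic-data
    generator (toy two-domain complexes, nitroxide-tag conformer ensembles,
    forward-simulated peak tables, planted-interface CSP tables and
    relaxation decay series) so that every stage can be validated against a
    known ground truth, plus small calculators for non-uniform-sampling
    sparsity planning and condensation-product mass checks.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
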