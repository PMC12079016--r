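Package: chargevar
Title: Conformer-Dependent Atomic Partial Charge Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how atomic partial charge assignments for small
    molecules vary with the input conformer and compute platform, and
    provides mitigations. Implements per-atom and per-bond charge
    variability metrics over ensembles of charge sets, an
    electrostatically-least-interacting (ELF-style) multi-conformer charge
    consensus, sigma-window stratified and similarity-aware ranked molecule
    selection, acyclic-bond truncation with hydrogen capping, SDF V2000 and
    JSON/CSV interchange, and a synthetic conformer/charge generator with a
    tunable contact-driven perturbation that supplies ground truth for the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
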