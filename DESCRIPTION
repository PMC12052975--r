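Package: abcgate
Title: Substrate Gating Analysis for Full-Size ABCG Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reconstruction of the computational chain used to
    dissect substrate gating at the extracellular gate of full-size ABCG
    (pleiotropic drug resistance) transporters. Provides a one-dimensional
    Langevin engine on analytic translocation free-energy landscapes,
    well-tempered metadynamics with multiple walkers and hill-summation
    free-energy-surface reconstruction, staged and constant-velocity steered
    pulling with force-window-corrected residue contact frequencies, an
    L2-regularised logistic model of per-residue transport importance, the
    electronic pocket-ligand binding-energy relation, and an evolutionary
    pipeline that screens ABCG-like protein panels for PDR signature motifs,
    maps extracellular-gate positions through alignments, tabulates per-taxon
    residue occurrence, and computes sequence-logo information content and
    consensus motifs. Deterministic synthetic-data generators emulate every
    input at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
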