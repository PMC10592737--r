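Package: contactbn
Title: Bayesian Network Analysis of Protein-Protein Interface Contact Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cooperative residue-residue contacts at protein-protein
    interfaces (notably GPCR:G protein complexes) from per-frame binary contact
    data. Detects typed interface contacts (salt bridges, hydrogen bonds, van
    der Waals, pi-stacking, cation-pi) from multi-model PDB coordinates,
    encodes them as binary fingerprint matrices, learns discrete Bayesian
    networks by score-based hill climbing with random restarts under a
    Dirichlet-multinomial (BDeu) marginal likelihood, and reports per-edge
    strengths on a per-observation scale. Downstream tools rank contact
    cooperativity (node strength), aggregate it over structural regions,
    moralize and compare networks across complexes via largest common
    subgraphs and Jensen-Shannon divergence of empirical joint distributions,
    classify dependencies as neighboring or allosteric by C-alpha distance,
    and assess model robustness by topology perturbation and frame
    resampling. A synthetic-fixture generator with planted dependency
    structure supports end-to-end validation without trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
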