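Package: mdain
Title: Allosteric Interaction Networks from Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies allosteric interaction networks in membrane transporters
    from molecular dynamics ensembles. Detects per-frame residue interactions
    (van der Waals contacts complemented by geometric hydrogen bonds), estimates
    per-condition interaction frequencies across replicas, tests frequency
    differences between conditions with replica-level statistics and FDR control,
    and coarse-grains significant pairs onto a transmembrane subsegment scheme to
    build signed difference networks. Also provides the accompanying geometric
    observables (vestibule water counts, cation binding-site classification,
    chi1 rotamers) and a 1-D weighted-histogram (WHAM) solver with block-error
    estimation for umbrella-sampling free-energy profiles, plus synthetic-fixture
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    boot,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
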