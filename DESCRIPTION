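Package: vicinalJ
Title: Ensemble-Averaged Vicinal J-Coupling Prediction and Epimer Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ensemble-averaged vicinal proton-proton coupling
    constants (3JHH) from conformer ensembles using the generalized
    Haasnoot-de Leeuw-Altona (HLA) Karplus equation with substituent
    electronegativity and orientation corrections, and scores candidate
    epimers of a stereocenter against measured couplings. Includes readers
    for multi-model PDB and multi-frame XYZ ensembles, signed torsion-angle
    geometry, quantitative J-based rules for olefinic E/Z and sp3
    diaxial-range classification, and a seeded von Mises rotamer-ensemble
    generator with known stereochemical ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
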