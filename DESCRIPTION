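Package: glycosurf
Title: Carbohydrate-Binding Site Prediction on Protein Surfaces from
    3-D Interacting-Atom Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts non-covalent carbohydrate-binding sites on protein
    structures. Every solvent-exposed protein atom is encoded with 37
    attributes derived from three-dimensional probability density maps of
    36 non-covalent interacting atom types (30 protein, 5 carbohydrate,
    water) plus a local-geometry term; one classifier (feed-forward
    neural network, support vector machine, or bagged resilient-propagation
    network ensemble) is trained per protein atom type; classifier outputs
    are calibrated to confidence levels with validation lookup tables;
    high-confidence atoms are clustered into surface patches and converted
    to residue-level predictions, benchmarked with the standard six
    two-class scores. Includes a deterministic generator of toy
    protein-sugar complexes so the whole pipeline is testable without any
    structure download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    digest,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
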