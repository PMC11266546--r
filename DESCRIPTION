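Package: mutstab
Title: Graph-Transformer Prediction of Protein Stability Changes with
    Thermodynamic Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of the thermodynamic stability change
    (ddG, kcal/mol) caused by single point mutations. Implements a distance-biased
    graph transformer over masked residue microenvironments (atom tokens with
    element, partial charge and solvent accessibility features), a Siamese
    regression head that contextualizes structural amino-acid embeddings against
    one microenvironment and decodes their difference into a ddG, thermodynamic
    permutation and reversibility data augmentation, leakage-aware dataset
    curation with a 30 percent sequence-identity barrier, evaluation metrics for
    stabilizing-mutation discovery, and deterministic synthetic-data generators
    that make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
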