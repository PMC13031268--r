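Package: swarmcell
Title: Decentralized (Swarm) Training of Cell-Type Classifiers for
    Multi-Study Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study decentralized ("swarm") training of cell-type
    annotation classifiers across several single-cell RNA-seq studies that
    cannot pool their raw data. Includes a synthetic multi-study count
    generator with batch effects, rare and missing cell types and planted
    low-quality cells; per-study quality control (MAD outlier filtering,
    mitochondrial-fraction rule), highly-variable-gene selection and a shared
    union feature space; a seed-deterministic multilayer-perceptron classifier
    trained with Adam; an in-process simulator of the swarm-learning protocol
    (private peer training with weighted parameter averaging at sync events);
    the Local_1/Local_2/Local_3/Swarm experiment grid; and evaluation via
    per-class and aggregate F1 scores, confusion matrices, a cell-type rarity
    index with its regression on F1, and Mann-Whitney comparisons between
    training settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
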