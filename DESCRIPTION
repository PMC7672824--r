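Package: goknn
Title: Protein Gene Ontology Prediction with Gapped-Dipeptide PSSM Features
    and k-Nearest-Neighbor Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations for proteins from
    sequence profiles. Each protein is represented by a term-frequency
    vector of gapped dipeptides computed from its position-specific
    scoring matrix (TFPSSM), reduced by principal component analysis,
    and classified by nearest-neighbor voting (single nearest neighbor,
    fixed-k, dynamic distance-threshold, and hybrid variants) with
    distance- or domain-overlap-based vote weights. Votes are propagated
    up the GO directed acyclic graph (Sum or Max merging), normalized to
    confidence scores, and evaluated protein-centrically with CAFA-style
    precision/recall curves and Fmax in full or partial mode. Includes
    Naive and BLAST-hit baselines, five-fold cross-validation utilities,
    readers and writers for OBO, PSI-BLAST ASCII PSSM, annotation TSV
    and CAFA prediction formats, and a seeded synthetic-benchmark
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
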