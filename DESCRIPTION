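Package: hypermol
Title: Fingerprint-Substructure Hypergraph Neural Networks for Molecular Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts molecules into hypergraphs whose nodes are circular
    (extended-connectivity) fingerprint substructures and whose links join
    substructures sharing atoms, then learns molecule-level representations for
    property prediction with fingerprint-level GCN or GIN message passing and
    sum pooling. Includes SMILES ingestion via OpenBabel, deterministic
    Bemis-Murcko scaffold splitting, a masked multitask binary cross-entropy
    trainer with Adam, ROC-AUC evaluation over multiple seeded runs,
    fingerprint length/radius sensitivity sweeps, and a synthetic
    motif-labelled molecule generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
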