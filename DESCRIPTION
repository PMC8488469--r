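Package: dhtppi
Title: Plant Protein-Protein Interaction Prediction from Evolutionary
    Profiles via the Discrete Hilbert Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions
    (PPIs) in plants. Each protein is encoded as a position-specific
    scoring matrix (PSSM) obtained from PSI-BLAST (or as a BLOSUM62
    substitution profile), condensed to a 20x20 matrix, and converted to
    a 400-dimensional "local energy" descriptor with a 2-D discrete
    Hilbert transform (the modulus of the 2-D analytic signal). Singular
    value decomposition reduces each descriptor from 400 to 300
    dimensions and protein pairs are represented by the 600-dimensional
    concatenation. A small feedforward neural network (merged or
    Siamese-fusion architecture, ReLU hidden layers, sigmoid output,
    Adam optimiser, dropout) classifies pairs; K-nearest-neighbour and
    random-forest baselines, comparator descriptors (DCT, FFT, Haar DWT,
    auto-covariance), five-fold cross-validated Acc/PR/Sens/Spec/MCC/AUC
    reporting, bipartite negative sampling and a fully synthetic
    planted-signal data generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
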