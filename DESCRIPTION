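Package: pepdesign
Title: Ensemble Classification and Diversity-Constrained Design of
    Antibody-Binding Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts high- versus low-affinity antibody binding of short
    peptides (15-mers over the 20 amino acids plus citrulline) with an
    ensemble of Platt-calibrated support vector machines trained on residue
    encodings (BLOSUM50 and reduced physicochemical matrices), AAIndex
    sliding-window features, docking-score histograms, and string kernels
    (k-spectrum, sparse spatial sample, bounded-range substring). Designs
    novel peptides of a desired binding class by diversity-constrained
    random walks in sequence space, and provides the accompanying
    evaluation machinery: grey-zone precision/recall/accuracy curves,
    permutation F1 tests, Hamming-graph maximal-independent-set diversity
    profiles, and positional residue-propensity matrices. A synthetic pool
    generator with planted k-mer motifs and bimodal intensities makes every
    component testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    kernlab,
    Matrix,
    Biostrings,
    seqinr,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
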