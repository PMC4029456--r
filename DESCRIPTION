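Package: enhancerPred
Title: Enhancer Activity Prediction from Chromatin Marks and Sequence Motif Affinities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised prediction of active cis-regulatory modules (enhancers)
    from the combination of windowed chromatin-mark signal (EPI features) and
    thermodynamic transcription-factor binding affinities computed with the
    TRAP occupancy model from position weight matrices (MOT features).
    Provides readers for FASTA/BED/bedGraph/JASPAR-PFM inputs, a synthetic
    data generator with planted motif and chromatin signal, length-matched
    negative-region sampling, random-forest / RBF-SVM / BDe-scored Bayesian
    classifiers, standard and reversed cross-validation, external validation,
    shadow-variable (Boruta-style) feature importance with false-discovery
    estimation, and mark/motif ablation protocols.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Epigenetics, Classification, FunctionalPrediction, Sequencing
RoxygenNote: 7.3.3
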