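Package: motifclust
Title: Alignment-Free Clustering of DNA Binding Motifs by a Genetic
    k-Medoids Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters transcription-factor binding motifs without alignment
    and without a guide tree. Position weight matrices are trimmed by
    information content, represented as k-mer frequency vectors, compared
    with cosine distance, and partitioned by a k-medoids local search
    embedded in a steady-state genetic algorithm whose silhouette-based
    fitness selects the number of clusters and their membership
    simultaneously. Clusters are summarised as familial binding profiles
    built by ungapped star alignment to the cluster medoid, and evaluated
    by nearest-neighbour retrieval accuracy, structural-class homogeneity,
    leave-one-out cross-validation and robustness to synthetic noise.
    Motifs are read and written in JASPAR PFM and TRANSFAC flat-file
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
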