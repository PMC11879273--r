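Package: norppa
Title: Mitogenome Diversity, Haplotype Networks and Skull Geometric
    Morphometrics for Ringed Seal Phylogeography
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for phylogeographic analysis of ringed
    seals (Pusa hispida) combining two arms. The population-genetics arm
    reads aligned mitogenomes, collapses haplotypes and computes diversity
    statistics (segregating sites, haplotype diversity, nucleotide
    diversity, mean pairwise differences, Ewens sampling probability),
    Hudson's Kst permutation test, Nei's net nucleotide divergence dA with
    subspecies and species thresholds, and builds median-joining haplotype
    networks. The geometric-morphometrics arm implements generalized
    Procrustes superimposition with object symmetry, allometry correction by
    regression on log centroid size, PCA, jackknife canonical-variate
    classification, Hotelling's T2 tests, Procrustes and Mahalanobis
    distances, and discriminant-vector angles. A seeded synthetic-data
    generator provides alignments and landmark datasets with known truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
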