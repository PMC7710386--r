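Package: patternblend
Title: Pattern Blending Analysis of Animal Skin Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how complex animal skin patterns (labyrinthine
    markings) can arise from the blending of simple motifs (dark and light
    spots), e.g. through hybridization. Provides a two-factor Turing
    reaction-diffusion simulator on grids, spheres and fused-blob meshes
    with spatially graded kinetics for in silico hybridization; pattern
    quantification via pattern lightness and an area-weighted isoperimetric
    pattern-complexity score; genus-level phylogenetic collocation
    statistics for binary pattern-motif tables (Jaccard, Sorensen-Dice,
    Simpson, log-likelihood, T and z scores, pairwise and triple);
    ABBA-BABA introgression statistics (Patterson's D with block-jackknife
    z scores, trio-level D_min, interclass heterozygosity); an eight-state
    continuous-time Markov model of correlated evolution of three binary
    motifs on phylogenies with independent, partially independent and
    dependent parameterizations; and seeded synthetic-data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ape,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
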