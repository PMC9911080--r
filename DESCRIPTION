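Package: pirnaHD
Title: Simulation and Analysis of piRNA-Mediated Transposon Silencing and
    Hybrid Dysgenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying P-element invasion biology at
    the level of ovarian small-RNA libraries and dysgenesis crosses. Simulates
    small-RNA sequencing libraries with known transposon-family composition,
    ping-pong pairing structure (10-nt 5' overlaps with 1U/10A biases),
    adapter contamination and sequencing error; processes reads (3' adapter
    trimming, length filtering, miRNA subtraction, ungapped mismatch-tolerant
    mapping to transposon consensus sequences at tiered stringency);
    quantifies family-level small-RNA abundance with reads-per-million
    normalization and a precision-weighted (voom-style) linear model for
    differential abundance against resistance phenotypes; computes per-family
    ping-pong signatures (5' overlap histograms, z-scores, nucleotide-bias
    fractions); and implements the cross-level statistics of hybrid
    dysgenesis assays (Fisher's exact test on reciprocal crosses, binomial
    GLM line effects, screen correlations, extreme-line classification) and
    qPCR relative quantification with Box-Cox transformation and ANOVA of
    splicing efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
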