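Package: topicbin
Title: Topic-Model-Based Binning of Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised taxonomic binning of metagenomic reads and contigs.
    Each read is represented by its tetranucleotide (4-mer) composition,
    transformed into a latent-topic distribution with a Latent Dirichlet
    Allocation model estimated by collapsed Gibbs sampling, and clustered
    with SKWIC, a K-means variant that learns per-cluster, per-dimension
    feature weights. Includes precision/sensitivity/F1 scoring of binnings
    against truth labels and a seeded synthetic-community simulator
    (Markov-chain genomes, configurable abundance ratios, read lengths and
    substitution error rates) so the whole pipeline can be exercised
    without external reference genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
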