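Package: genetiler
Title: Self-Training Prokaryotic Gene Prediction by Dynamic-Programming Tiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of protein-coding genes in bacterial and
    archaeal genomes. Given nucleotide contigs and an NCBI translation table,
    the package learns an organism-specific model with no user-supplied
    parameters: a GC frame-plot codon-position bias, an in-frame hexamer
    (5th-order Markov) coding model, start-codon type weights, binned
    Shine-Dalgarno ribosome-binding-site motif weights (with an exhaustive
    secondary motif finder for organisms that do not use the Shine-Dalgarno
    signal), and an upstream position-weight matrix. Genes are called by
    dynamic programming over candidate start/stop nodes with operon-distance
    modifiers and explicit same-strand and opposite-strand overlap rules,
    including partial genes at contig edges. Includes a deterministic
    synthetic-genome generator with planted genes for benchmarking, GFF3 and
    protein FASTA writers, per-start diagnostics, and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
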