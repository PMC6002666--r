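Package: pangrowth
Title: Pan-Genome Rarefaction, Openness Inference, and Genome Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds ortholog presence/absence matrices from all-vs-all
    protein hit tables, computes combinatorial core-, new-, and pan-gene
    rarefaction observation sets with median summaries and normality
    diagnostics, fits exponential-decay core/new-gene models and the
    Heaps power law by multistart nonlinear least squares to extrapolate
    core-genome size and decide whether a bacterial pan-genome is open or
    closed, and provides assembly statistics (N50/N90/GC) and
    tetranucleotide z-score signatures for strain characterisation.
    Includes simulators for presence/absence matrices, hit tables, and
    contig sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    minpack.lm,
    Biostrings,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
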