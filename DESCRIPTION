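Package: paralocus
Title: Presence-Absence Inference and Diversity Analytics for Tandemly
    Duplicated Paralog Loci from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tandemly duplicated multigene loci (such as
    the cattle killer-cell immunoglobulin-like receptor complex) from short,
    possibly ancient, sequencing reads. Provides a synthetic-locus simulator
    with block-duplication structure and ancient-DNA-like read sampling, an
    exact ungapped read mapper with unique-mappability classification, depth
    and sliding-window coverage profiling against a simulated tiling control,
    majority-rule consensus and frequency-threshold variant calling,
    group-exclusive read filtering with diagnostic-SNP consistency scoring
    for per-paralog presence/absence calls, and locus diversity analytics
    (dot-plot and sliding-window identity, substitution and NS/S counting,
    p-distance matrices, ITIM and transmembrane motif scans, open reading
    frame integrity classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
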