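Package: scafflink
Title: Alignment-Free Genome Scaffolding with Paired k-mers from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients the contigs of a draft genome assembly into
    scaffolds using long, error-containing sequences (nanopore or PacBio
    reads, or another assembly draft) without alignment or base correction.
    Spaced k-mer pairs are harvested from the long sequences at a fixed
    5'-to-5' distance, matched against a Bloom filter of assembly k-mers,
    placed uniquely on contigs, and converted into distance-validated,
    oriented contig links from which scaffolds are laid out greedily under
    minimum-support and ambiguity-ratio guards. Also provides a parametric
    simulator of nanopore-like base-calling errors (Poisson/Weibull/geometric
    run-length mixtures) together with maximum-likelihood fitting and
    Kolmogorov-Smirnov diagnostics, and synthetic genome fixtures, so the
    scaffolder is fully testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
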