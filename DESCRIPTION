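Package: splinter
Title: Splice-Aware Causal Network Inference from Domain-Resolved
    Interaction Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the subnetwork of domain-domain and protein-protein
    interactions that connects an upstream perturbation to significantly
    regulated transcription factors, while accounting for alternative
    splicing: protein domains whose mapped exons or transcripts show
    significant exclusion are either forbidden (hard mode) or penalized
    (soft mode) during selection. Transcription-factor activities are
    scored against a regulon prior with an empirical permutation null;
    exon and transcript evidence is combined per domain with Fisher's
    method; the selection itself is an integer linear program solved
    exactly by a built-in branch-and-bound, with multi-solution
    enumeration, consensus edge weights, splice-aware versus
    splice-unaware network differencing, and hypergeometric
    over-representation analysis of inferred nodes. Includes a seeded
    synthetic scenario generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
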