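Package: paralogscope
Title: Selective Constraint and Expression Similarity Analysis of Duplicate Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing duplicated gene pairs in bacterial genomes
    with multipartite architectures. Implements pairwise Ka/Ks estimation at
    the codon level (Nei-Gojobori counting, a modified Yang-Nielsen estimator
    under the Tamura-Nei 1993 substitution model, and its gamma-rates
    variant), synonymous-saturation filtering, omega-based selection
    classification with replicon-group summaries and length binning, and an
    expression-similarity arm (z-score normalisation, cosine similarity,
    quadrant classification, deterministic spherical k-means initialised by
    hierarchical agglomerative clustering, and symmetric cluster matching).
    Includes simulators for codon-sequence pairs with known evolutionary
    parameters and for replicated expression matrices with latent cluster
    structure, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
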