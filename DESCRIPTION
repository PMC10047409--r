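Package: cernakit
Title: Simulation and Inference of miRNA-Mediated ceRNA Networks from Small
    RNA Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for inferring lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) networks from staged small RNA sequencing
    experiments. Covers raw read cleaning and mature miRNA quantification,
    trimmed-mean library normalization, an exact conditional
    negative-binomial test for pairwise stage comparisons, temporal
    expression profile classification, seed-match miRNA target-site
    prediction with canonical and noncanonical site classes,
    directionality-constrained pairing and triplet assembly into a typed
    bipartite-layered network with degree-based hub ranking, and the assay
    arithmetic used for validation (2^-ddCt relative quantification and
    dual-luciferase ratios). Includes a seeded synthetic-data generator
    that plants differential expression, binding sites, and sponge
    triplets with machine-readable ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
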