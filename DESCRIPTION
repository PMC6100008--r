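Package: nsfpscreen
Title: Neighbouring-Substructures Fingerprints and Selectivity Screening
    Cascades for GPCR Ligand Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hierarchical ligand- and structure-based virtual
    screening of subtype-selective G-protein coupled receptor ligands. The
    package computes the Neighbouring Substructures Fingerprint (NSFP), a
    connectivity-aware substructure fingerprint whose features are adjacent
    doublets and triplets of SMARTS-key matches; trains kernel classifiers
    (support vector machines with Tanimoto, Sorensen and radial basis
    kernels, Bernoulli naive Bayes, and a closed-form kernel discriminant)
    selected by cross-validated Matthews correlation; applies a two-stage
    activity-then-selectivity classification cascade; and post-processes
    docking poses with protein-ligand interaction filters, per-receptor
    ranking, rank-difference consensus scoring, and leader-clustering
    diversity selection. A seeded synthetic-data module generates molecule
    libraries, affinity tables and docking pose sets with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    igraph,
    kernlab,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    e1071,
    optparse
Config/testthat/edition: 3
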