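Package: phenosim
Title: Benchmarking Ontology-Based Semantic Similarity on Patient Phenotype Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A platform for benchmarking configurations of ontology-based
    semantic similarity on patient phenotype profiles. Loads an OBO-format
    subsumption taxonomy (such as the Human Phenotype Ontology), computes
    corpus-based and structural information-content measures, pairwise
    term-term and groupwise profile-profile similarity measures, and
    evaluates every configuration on a shared-primary-diagnosis ranking
    task using global AUC, mean reciprocal rank, and top-k accuracy with
    parametric confidence intervals. Includes a synthetic-data generator
    that emulates noisy text-derived phenotype profiles, so the whole
    pipeline can be exercised without access to restricted clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
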