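Package: phenorank
Title: Phenotype Semantic Similarity and Disease Ranking over the Human
    Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes phenotype-term and phenotype-set semantic similarity
    over an ontology of phenotypic abnormalities (the Human Phenotype
    Ontology or any OBO-format is_a hierarchy).  Term information content
    blends gene and disease annotation sources; is_a edges are weighted by
    the TF-IDF cosine similarity of the endpoint definitions; term
    similarity is path-constrained (ancestor/descendant reachability with a
    depth-normalised distance penalty); set similarity is a symmetric
    best-match average weighted by the pointwise mutual information of
    co-annotation.  Ships a simulator for optimal, noisy and imprecise
    patient phenotype profiles, synthetic ontology/corpus fixtures, and a
    disease-ranking evaluation with cumulative rank distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
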