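Package: netaligner
Title: Pairwise Alignment of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise alignment of protein-protein interaction networks of
    arbitrary topology (interactome-to-interactome, complex-to-interactome,
    pathway-to-interactome, inter- or intra-species). Homologous protein
    pairs become alignment-graph vertices with probabilities calibrated
    from BLAST E-value likelihood ratios (isotonic regression smoothing);
    conserved and likely-conserved interactions become edges, the latter
    predicted from the difference of Grishin evolutionary distances.
    Alignment seeds (connected components) are extended with gap and
    mismatch edges through bounded highest-reliability paths, solutions
    are scored by a vertex/edge log-probability balance, and significance
    is assessed with a topology-preserving Monte-Carlo permutation test.
    Includes benchmark evaluation rules (coverage, precision/recall at
    complex, protein and interaction level) and a synthetic-data generator
    with planted conserved modules for self-contained testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
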