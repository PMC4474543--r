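Package: oncotopo
Title: Mutation-Frequency and Network-Topology Profiling of Cancer Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative characterization of cancer gene sets (tumor
    suppressors, oncogenes, drug targets, essential genes, and the network
    complement) by somatic-mutation frequency and protein-protein
    interaction network topology. Reads interaction networks (edge-list
    TSV, PSI-MI TAB, SIF), gene lists (GMT, one-per-line) and MAF-like
    somatic mutation tables; computes per-gene and per-set mutation
    frequencies with Kolmogorov-Smirnov set comparisons; profiles degree,
    betweenness, clustering coefficient and mean shortest-path distance;
    measures shortest-path proximity of gene sets to a drug-target set;
    and extracts a node-weighted Steiner subnetwork connecting two
    terminal sets with the Klein-Ravi spider-merge approximation,
    categorizing induced edges and correlating subnetwork degree with
    mutation frequency. A seeded synthetic-data module generates
    scale-free networks, hub-biased planted gene sets and Bernoulli
    mutation tables so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
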