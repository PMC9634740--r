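Package: netpharm
Title: Network-Pharmacology Screening of Herbal Compounds Against Disease Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable network-pharmacology inference chain for herbal
    medicine target prediction: ADMET eligibility screening of compound
    tables on oral bioavailability and drug-likeness, multi-database
    disease-target union and drug-disease intersection with Venn-region
    accounting, hypergeometric over-representation analysis with
    Benjamini-Hochberg q-values, six node-centrality measures on
    protein-protein interaction networks (betweenness, closeness, degree,
    eigenvector, local average connectivity and edge-clustering-based
    network centrality) with iterative median hub screening, bipartite
    compound-target network construction, and classification and ranking of
    molecular-docking binding energies. A synthetic-data module generates
    every input with planted structure so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
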