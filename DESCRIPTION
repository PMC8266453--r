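Package: netpharm
Title: Network Pharmacology Pipelines for Herbal Compound-Target-Pathway
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of the network-pharmacology
    inference chain used to study multi-component herbal medicines:
    ADME-based compound screening (Lipinski rule of five plus BOILED-Egg
    gastrointestinal absorption), construction of compound-target bipartite
    networks, merging of disease-target lists from multiple curated sources,
    confidence-score filtering of protein-protein interaction networks,
    topology-based key-node selection (degree, betweenness, closeness
    against median or mean thresholds), hypergeometric over-representation
    analysis of overlap gene lists with Benjamini-Hochberg correction, and
    tripartite compound-target-pathway network analysis.  A synthetic-data
    module generates inputs with the statistical structure the pipeline
    assumes (planted PPI hubs, spiked gene sets, bipartite drug-target
    graphs) together with ground-truth manifests, so every stage is
    testable without access to external web servers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
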