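Package: ddsnet
Title: Drug-Drug Similarity Networks for Network-Based Drug Repositioning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds tripartite drug-gene-disease association graphs from
    tab-separated interaction tables, projects them onto a weighted
    drug-drug similarity network (edge weight = number of diseases
    reachable from both drugs via drug-gene-disease paths), detects drug
    communities by cosine vertex-similarity hierarchical agglomeration
    with a modularity-optimal dendrogram cut, filters communities by
    connectivity and size, labels each community with its dominant ATC
    level-1 code, classifies drugs as label-matched or repositioning
    candidates, extracts top ATC level-4 codes with their mapped protein
    targets, and constructs Boolean PubMed queries for literature
    validation of candidates. Includes a planted-structure synthetic data
    generator for offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, Pharmacogenomics
RoxygenNote: 7.3.3
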