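Package: spreadRank
Title: Influential-Spreader Ranking in Networks via a DEMATEL Gravity Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies influential spreaders in undirected networks with a
    DEMATEL-based gravity model: pairwise gravity interactions (degree product
    over squared geodesic distance) form a direct-relation matrix whose
    normalized Neumann series yields total direct-plus-indirect influence;
    node importance is the sum of influence exerted and received. Ships the
    six standard comparison centralities (degree, betweenness, closeness,
    eigenvector, gravity, eigenvector-weighted gravity), a discrete-time
    susceptible-infected simulator for ground-truth spreading capacity,
    Kendall rank-correlation evaluation, Pajek and edge-list I/O, and seeded
    synthetic-network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'graph.R'
    'baselines.R'
    'io.R'
    'synthetic.R'
    'si.R'
    'evaluation.R'
    'cli.R'
    'dematel.R'
    'spreadRank-package.R'
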