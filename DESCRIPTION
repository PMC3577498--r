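Package: litnet
Title: Literature Co-Occurrence Mining for Gene-Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Thesaurus-based concept tagging of titled abstracts and
    co-occurrence counting; pairwise association scoring as lift rescaled
    onto a 0-100 R-scaled score with literature-count thresholds; rs-weighted
    gene-gene literature networks with keyword annotation, hub detection,
    power-law degree analysis and betweenness centrality; hypergeometric
    keyword enrichment of gene sets against drug and disease vocabularies;
    disease-profile clustering by correlation distance and complete linkage
    with multiscale-bootstrap AU/BP cluster support; and a neighbor-weighted
    literature score for ranking genes jointly by direct and neighborhood
    evidence. Includes a synthetic corpus generator with planted ground
    truth and a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
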