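Package: hubdyn
Title: Date and Party Hub Analysis of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes hubs in protein-protein interaction networks by
    their co-expression with interaction partners (avPCC) and classifies them
    into date (intermodular) and party (intramodular) hubs. Provides network
    ingestion and degree-preserving null models, expression-compendium
    processing with missing-data Pearson correlations, node-level topology
    (betweenness, local clustering, participation coefficient over a
    modularity-selected clustering), set-level density/expansion and
    hub-removal experiments with empirical resampling p-values, information
    content based functional similarity and broad-term GO enrichment,
    Spearman and partial Spearman correlation analyses with randomized-network
    controls, cross-species conservation tests over ortholog pairs, and a
    synthetic-world generator that emulates the statistical structure of real
    interactomes and expression compendia for fully self-contained testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
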