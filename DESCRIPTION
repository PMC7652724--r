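Package: funregnet
Title: Orthology-Based Inference of Fungal Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks for fungal genomes by
    transferring curated transcription-factor / target-gene interactions from
    model species through ortholog tables, corroborating each inferred edge by
    position-weight-matrix scanning of 1000-bp promoter regions with exact
    per-site p-values computed by dynamic programming, and analysing the
    resulting network (degrees, centralities, clustering, weakly connected
    components, Louvain communities, hypergeometric term enrichment).
    Includes transcription-factor family classification against a curated
    DNA-binding-domain catalog and a seed-reproducible synthetic-fixture
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
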