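Package: bihemi
Title: Bilateral Transcriptomic Response Analysis After Unilateral Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-group (ipsilateral, contralateral,
    naive) expression studies of unilateral brain injury. Implements
    detection-call presence filtering and signed fold-change screening of
    MAS5-style signal matrices, the piecewise ipsilateral/contralateral
    fold-ratio statistic that classifies bilaterally changed genes as
    responding similarly or differently across hemispheres, gene-set overlap
    summaries with hypergeometric enrichment, and a degree-based gene
    interaction hierarchy that tiers genes of interest by their direct
    connections in an interaction network. Ships synthetic-data generators
    with known ground truth for expression matrices and tiered networks, plus
    curated example tables from a rat controlled cortical impact microarray
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
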