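Package: degNetRank
Title: Two-Round Network Prioritization of Differentially Expressed Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes differentially expressed genes on a protein-protein
    interaction network in two screening rounds: Gene Ontology ratio scoring
    with percentile-rank screening, then a composite of six node centralities
    (degree, betweenness, closeness, radiality, stress, eigenvector), followed
    by MCODE-style molecular-complex detection and hypergeometric
    over-representation testing. Includes a synthetic-data generator with
    recorded ground truth (regulated gene sets, planted dense modules, planted
    enriched terms) so the full pipeline runs and is testable without external
    databases, plus comparative-Ct relative quantification for qPCR
    validation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
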