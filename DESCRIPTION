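Package: semhub
Title: Cross-Domain Literature Mining for Drug Adverse-Event Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining drug adverse-event (AE) signals from biomedical
    text at two scales. The corpus arm clusters drug-specific abstracts via a
    bounded-vocabulary TF-IDF representation and k-means, then profiles AE terms
    per cluster with fold changes and pairwise chi-square tests. The
    knowledge-graph arm ranks candidate conditions against target concepts in a
    typed predication graph using length-2 metapath HeteSim relevance with a
    novelty score, proposes unpublished links with a TransE embedding, and
    extends reach through hub-node neighborhoods whose per-hub rankings are
    normalized, aggregated, tiered (top 1%/5%/10%) and mapped to physiological
    foci. A synthetic-data module generates corpora and typed graphs with
    planted ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
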