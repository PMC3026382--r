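Package: pathmarker
Title: Discriminative Subnetwork Marker Discovery in Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies non-overlapping subnetwork markers that discriminate
    two phenotypes by overlaying gene expression on a protein-protein
    interaction network. Per-gene evidence is a log-likelihood ratio under
    class-conditional Gaussian models; candidate linear paths are scored by a
    correlation-weighted sum of absolute t-statistics with a trade-off
    parameter theta; a beam-style dynamic program finds top-scoring simple
    paths, which are greedily merged into subnetworks whenever the merge
    improves discriminative power by a configurable factor. Includes baseline
    marker schemes, a nested cross-validation harness with forward feature
    selection by AUC, and seeded generators of synthetic networks and
    expression data with planted discriminative modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
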