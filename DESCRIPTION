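Package: causalTF
Title: Causal Transcription-Factor Inference by Downstream Gene-Set
    Enrichment over Multi-Layer Regulation Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers candidate causal transcription factors (TFs) from a list
    of differentially expressed genes by integrating TF-DNA interactions
    with post-translational-modification (PTM) edges. For each TF, six
    hierarchical downstream gene-set models (direct targets through a
    three-layer cascade, bounded at TF-to-TF path length two) are
    constructed; each model's overlap with the DEG list is scored with a
    hypergeometric upper-tail test; models whose candidate-wide p-value
    distribution departs from the direct model are filtered out by a
    Wilcoxon rank-sum acceptability criterion; and TFs are ranked by their
    minimum acceptable-model p-value. Ships a synthetic regulatory-network
    and perturbation simulator with known ground truth, plus an evaluation
    harness (confusion counts, Jaccard score, prediction rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, NetworkInference, Transcription,
    GraphAndNetwork, SystemsBiology
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
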