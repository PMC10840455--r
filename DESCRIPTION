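Package: microsig
Title: Microbial Signature Discovery from Tumor Microbiome Abundance via
    Heterogeneous Graph Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumor samples by cancer type from intratumoral microbial
    abundance matrices using a heterogeneous graph transformer over species and
    sample nodes, with metabolic (shared-compound) and phylogenetic
    (shared-genus) species-species edges as auxiliary structure, and extracts
    cancer-associated microbial signatures from the learned species-to-sample
    attention scores by high-attention thresholding and one-sided hypergeometric
    enrichment. Includes autoencoder-based initial node embeddings, focal-loss
    training with Adam and reduce-on-plateau learning-rate scheduling, a
    planted-marker synthetic data generator, and tab-delimited exports for
    Cytoscape and UpSet visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
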