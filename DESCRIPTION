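Package: ddipool
Title: Convolutional Sentence Classification with Pluggable Pooling for
    Drug-Drug Interaction Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relation extraction of drug-drug interactions (DDI) from
    annotated biomedical sentences with a convolutional neural network over
    word and position embeddings. Implements the full pipeline: parsing of
    DDIExtraction-2013 style XML corpora, candidate pair generation with
    entity blinding, rule-based negative-instance filtering (coordination
    and hyponymous apposition), fixed-length encoding with regrouped
    relative positions, multi-width convolution, four pooling operators
    (max, average, attentive, and the max+attentive combination), dropout
    and softmax classification trained with Adam, and micro-averaged
    evaluation in the DDI-challenge style. A seeded generator of synthetic
    DDI-style corpora with known ground truth provides a download-free
    test surface, so the effect of the pooling choice can be measured
    reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
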