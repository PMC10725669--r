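Package: pharddi
Title: Pharmacological-Representation LSTM Networks for Drug-Drug
    Interaction Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts drug-drug interactions (DDIs) from annotated
    biomedical text. Implements a pharmacological representation that
    augments randomly encoded token embeddings with four target-drug
    filters (target, neighbor, path, and importance), a gated recurrent
    cell with a dedicated pharmacological gate plus ten published LSTM
    variants (ablated gates and activations, coupled input-forget gate,
    peephole connections, full gate recurrence), a multi-task training
    scheme with SoftMax heads for the coarse-grained (binary) and
    fine-grained (five-type) DDI tasks, and an evaluation suite with
    per-class and micro/macro averaged F-scores, a cross-corpus
    scalability score, multi-run reproducibility summaries, and Welch's
    t-test. A synthetic-corpus generator emulating the DDIExtraction XML
    dialect supports end-to-end testing without the licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
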