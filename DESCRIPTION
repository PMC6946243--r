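Package: litGeneNet
Title: Literature Mining of Gene-Disease Associations and Co-Citation
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies disease-associated genes from a corpus of
    bibliographic records by dictionary-based gene mention tagging with
    synonym normalization and conjunction resolution, scores gene-disease
    co-occurrence with an exact hypergeometric tail statistic, performs
    hypergeometric over-representation analysis of the significant gene
    set against GO and pathway gene-set collections, and builds a merged
    gene network from curated relations (KGML, protein-protein
    interaction tables) and sentence-level co-citation, with power-law
    degree-distribution fitting and hub-gene ranking. A synthetic-corpus
    generator with planted associations and a planted scale-free
    co-mention graph provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'corpus-io.R'
    'ner.R'
    'cooccurrence.R'
    'enrichment.R'
    'network.R'
    'synthetic.R'
    'pipeline.R'
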