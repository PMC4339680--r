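Package: netsim
Title: Gene Ontology Term Similarity from Annotations and Gene
    Co-Function Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures semantic similarity between Gene Ontology terms by
    combining the ontology graph, gene annotations, and a weighted gene
    co-function network. Implements the NETSIM measure (gene-set distance
    on the network, path-constrained annotation, and a combined
    information-content score), its ablation variants, and the Resnik,
    Schlicker and Wang baselines; aggregates term similarities into
    gene-to-gene functional similarity with leave-one-out; and evaluates
    measures on metabolic reaction maps with a logged fold-change
    benchmark and a genome-specificity statistic. Includes seeded fixture
    generators (ontology, annotations, network, reaction map) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
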