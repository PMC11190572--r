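Package: phenoscribe
Title: Computable Species Descriptions from Semantic Phenotype Scripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolchain for individual-based (ABox) computable species
    descriptions. Provides a small domain-specific language for semantic
    phenotype statements built on entity-quality annotation with OBO-style
    ontology terms, a compiler from parsed descriptions to an OWL knowledge
    graph of ontology individuals, shape-constraint validation, a
    lightweight materializing reasoner with transitive parthood and
    existential skolemization, annotated natural-language generation from
    the knowledge graph, semantic count queries over phenotypic
    characteristics and body regions, and nanopublication packaging of
    per-species assertions as TriG named graphs. Ships a bundled fixture
    mini-ontology and a synthetic description generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
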