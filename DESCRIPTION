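Package: embryofab
Title: Ontology-Driven 3D Modeling of Human Embryo Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative RDF-style ontology of human embryo developmental
    anatomy (anatomical entities, Carnegie-stage time, geometric primitives,
    evolution processes, diseases), a forward-chaining engine that saturates
    the ontology with a set of fifteen safe (Datalog) inference rules, a
    SPARQL-subset query layer, and a procedural engine that turns the
    saturated knowledge graph into animated 3D scenes of organ development:
    growth, migration, rotation, fixation constraints and meta-ball division,
    including disease-driven inactivation of developmental processes.
    Ships a programmatically regenerated reference embryo (urogenital system)
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
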