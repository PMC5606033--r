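Package: omicsFed
Title: Linking and Federated SPARQL Querying of Multi-Omics Cancer Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts tab-separated multi-omics cancer tables (somatic
    mutation, copy-number variation, gene expression, promoter methylation,
    pathway annotation) into named-graph RDF quads with a deterministic
    IRI-minting scheme, discovers owl:sameAs links between sources by
    exact-key and genomic-position rules, and answers basic-graph-pattern
    SPARQL SELECT queries over a federation of sources via two-level
    (endpoint, named-graph) source selection, exclusive-group query
    planning and sameAs-aware mediator hash joins. Ships a synthetic
    federation generator with planted links and a union-store oracle for
    verifying federated results, plus parameterised implementations of
    promoter-methylation, mutation-locus and pathway query templates and
    RPKM/mutation-frequency gene prioritisation filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'omicsFed-package.R'
    'terms.R'
    'quadstore.R'
    'records.R'
    'rdfizer.R'
    'linker.R'
    'sparql.R'
    'federator.R'
    'querybank.R'
    'synth.R'
    'fixture.R'
    'config.R'
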