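Package: omigraph
Title: Queryable RDF Integration of Multi-Omics Results and Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts genome annotations (GFF3) and tabular single-omics
    results (differential expression, differential methylation, chromatin
    accessibility peaks, chromatin-conformation switches, design tables)
    into a linked RDF graph organised around a five-block integration
    schema with FALDO genomic locations and a Condition/Context/Contrast
    experimental-design vocabulary. Ships an embedded named-graph triple
    store with a SPARQL subset engine, a query-graph compiler that turns
    abstract entity/filter/overlap graphs into SPARQL (including
    genomic-interval overlap joins), a synthetic-fixture generator with
    planted ground-truth counts, and reproduction suites for two published
    multi-omics case studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
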