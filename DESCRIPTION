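Package: hedr
Title: Hierarchical Event Descriptor (HED 2.0) Annotation Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for annotating experimental and real-world events with
    Hierarchical Event Descriptor (HED 2.0) tags. Provides the schema model
    for hierarchical controlled vocabularies (XML and MediaWiki dialects,
    unit classes, node attributes), a parser and normalizer for HED
    annotation strings (comma lists, one-level parenthesized groups,
    tilde-separated subject-predicate-object clauses), schema-driven
    validation of strings and tab-separated event tables with remapping of
    invalid tags, code-to-tag map application across event files, tag-prefix
    queries with epoch extraction and tag-usage summaries, and export of
    annotations as RDF triples (N-Triples, Turtle). Ships a compact fixture
    vocabulary and seeded generators for schemas and event tables with an
    error-injection ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
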