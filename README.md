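# hedr — Hierarchical Event Descriptor (HED 2.0) annotation tools for R

EEG experiments — and increasingly, experiments in real and virtual
worlds — produce streams of *events*: stimulus presentations, participant
responses, environmental happenings. Sharing and meta-analyzing such data
requires annotating each event in a vocabulary that is common across
laboratories yet rich enough to capture what actually happened. The
Hierarchical Event Descriptor (HED) system answers this with a
semi-structured controlled vocabulary: a tree of tags up to seven levels
deep (e.g. `/Item/2D shape/Ellipse/Circle`), extensible at leaves and at
designated nodes, with `#` wildcard nodes that take values, optionally
constrained to be numeric or carry units from a named unit class.

An event annotation (a *HED string*) is a comma-separated list of tags and
parenthesized tag groups. A group binds an item to its attributes, and may
contain up to three tilde-separated clauses forming a
subject–predicate–object statement:

```
(/Item/Object/Person ~ /Action/Type/Eat ~ /Item/Object/Animal/Fish)
```

distinguishes "man ate fish" from "fish ate man" — clause order is
meaning, so normalization sorts comma lists but never reorders clauses.

`hedr` implements the complete toolchain around this model, for
methodologists and data curators who tag event tables rather than drive a
GUI:

* **Schema model** — read/write vocabularies in an XML dialect and a
  MediaWiki text dialect, resolve tag paths (`exact`, `valueMatch`,
  `extension`, `miss`), search node names, collapse to a level, and
  self-check a schema (`parse_schema_xml()`, `parse_schema_wiki()`,
  `hed_locate()`, `schema_search()`, `nodes_at_level()`, `check_schema()`).
* **Annotation strings** — parse, serialize canonically, normalize to a
  unique text, substitute `#` wildcard values, parse values against unit
  classes (`parse_hed()`, `normalize_hed()`, `substitute_value()`,
  `parse_hed_value()`).
* **Validation and correction** — check tags, strings and whole
  tab-separated event tables against a schema, producing errors, warnings,
  extension records and a `remap` list of unique invalid tags; apply
  corrections across a file in one step; translate vocabularies by longest
  prefix (`validate_hed_string()`, `validate_event_table()`,
  `apply_remap()`, `translate_tags()`).
* **Event tables and tag maps** — read/write TSV event files (codes or
  latencies as identifiers), apply code→tags maps to whole collections
  (`read_events_tsv()`, `load_tagmap()`, `apply_tagmap()`,
  `tag_directory()`).
* **Query and epoching** — select events by tag-prefix queries, extract
  time-locked epoch windows, summarize tag usage by hierarchy level
  (`hed_query()`, `select_events()`, `extract_epochs()`,
  `summarize_tags()`).
* **RDF export** — emit subject–predicate–object triples for annotated
  events (types, labels, comments, the implied relations between top-level
  classes, and S-P-O statements from tilde groups) as N-Triples or Turtle
  (`instance_triples()`, `write_ntriples()`).
* **Fixtures and generators** — a bundled ~100-node fixture vocabulary,
  the worked-example annotations, and seeded generators for schemas and
  event tables with an exact error-injection ledger (`fixture_schema()`,
  `gen_schema()`, `gen_events()`).

## Worked example: validate, correct, revalidate

```r
library(hedr)
schema <- fixture_schema()

ann <- paste0("/Evnt/Category/Experimental stimulus, /Event/Label/square, ",
              "/Event/Description/A square is shown, ",
              "/Item/2D shape/Rectangle/Square")
validate_hed_string(ann, schema)
#> Errors (2)
#>   UNKNOWN_TAG: tag not in schema: /Evnt/Category/Experimental stimulus
#>   REQUIRED_MISSING: annotation lacks a required /Event/Category tag
#> Warnings (0)
#> Extensions (0)
#> Remap (1)
#>   /Evnt/Category/Experimental stimulus
```

The misspelled `/Evnt/...` tag is unknown, and because of it the
annotation lacks the required `/Event/Category`; the `remap` section lists
each unique invalid tag once, ready to become a correction table:

```r
fix <- hed_remap("/Evnt/Category/Experimental stimulus",
                 "/Event/Category/Experimental stimulus")
corrected <- apply_remap("1.0\t<the annotation above>", fix, tag_columns = 2)
validate_event_table(corrected, 1, 2, FALSE, schema)
#> Errors (0)
#> Warnings (0)
#> Extensions (0)
#> Remap (0)
```

Zero errors and an empty remap: the file is clean, and `apply_remap()` is
idempotent so re-running the correction changes nothing. The same loop
runs from the shell as `hed validate` / `hed remap`, and continues with
`hed tag` (apply a code→tags map) and `hed epoch` (extract windows
time-locked to events matching a tag prefix).

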