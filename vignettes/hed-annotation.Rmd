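---
title: "Annotating events with hierarchical event descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating events with hierarchical event descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedr)
```

## The annotation model

A HED vocabulary is a forest of named nodes. A *tag* is a `/`-joined path
into that forest; annotating an event means attaching a comma-separated
list of tags and parenthesized tag groups to it. The model has three
load-bearing ideas:

1. **Semi-structure.** The vocabulary is enforced (validation rejects
   unknown paths) but extensible: any leaf, and any node carrying the
   `extensionAllowed` attribute, accepts user-defined descendants. Such
   tags are reported as *extensions* — a third severity besides errors and
   warnings — because they are legal but worth surfacing for later
   community curation.
2. **Wildcard values.** A node whose only child is named `#` takes a
   user-supplied value (`/Attribute/Presentation fraction/0.1`). The `#`
   node may require the value to be numeric (`isNumeric`) and may bind it
   to a *unit class*: a named set of allowed units with a default, so
   `/Attribute/Duration/5` means 5 seconds and `/Attribute/Duration/5 ms`
   is five milliseconds, while `/Attribute/Duration/5 parsecs` is a unit
   error. Single-symbol units such as `$` prefix the number without a
   space (`/Participant/Effect/Cognitive/Reward/$10`).
3. **Groups and clauses.** Parentheses bind an item to its attributes
   within one event. One level of nesting is allowed, deliberately: it
   forces annotations into simple sentences. Inside a group, up to three
   tilde-separated clauses form a subject–predicate–object statement,
   whose clause order is semantic and never reordered.

Validation enforces per-tag rules (unknown tags, non-numeric values, bad
units, values on nodes that take none, `childRequired` nodes used bare,
over-long `/Event/Label` values) and per-annotation rules: every event
annotation must include tags under the required `/Event/Category` and
`/Event/Label` nodes, should include `/Event/Description` (a warning when
missing), and must not repeat a `unique`-attributed node such as
`/Event/Description`.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| label length limit | `validate_tag()` | 20 characters | labels are short study-local identifiers; values of length 20 or more draw a warning, not an error, because automated processing ignores labels |
| clause limit | `parse_hed()` | 3 | subject, predicate, optional object |
| nesting limit | `parse_hed()` | 1 level | simple-sentence discipline |
| `pre`, `post` | `extract_epochs()` | 0 s | epoch window half-widths around the event latency, in seconds |
| `latency_unit`, `sampling_rate` | `read_events_tsv()` | seconds | identifiers in samples are divided by the rate; the division is exact for integer samples and rates |
| `level` | `summarize_tags()`, `nodes_at_level()` | — | hierarchy depth for collapsing; 1 = the ten top-level classes |
| `base`, `inverse`, `type_spelling` | `instance_triples()` | `…/schema/v2/`, off, `rdf` | see below |

The unit-class registry ships with time (s, ms; default s), physicalLength
(m, cm, mm; m), angle (degree, radian; radian), frequency (Hz), area
(m^2), volume (m^3), currency ($), velocity (m-per-s) and jerk
(m-per-s^3). Units are SI and the defaults are the base units; unit
comparison is case-sensitive because unit symbols are case-significant
(Hz, not hz).

## Design decisions

Several points are genuinely open in the HED 2.0 description; the package
fixes them as follows, once, and the tests pin the choices.

* **Serialization dialects.** The XML dialect uses one element per node
  with `<name>`/`<description>` child elements, attribute flags as
  lowerCamelCase XML attributes, and a trailing `<unitClasses>` section.
  The wiki dialect uses `'''Name'''` headings for roots, `*`-depth list
  lines, `{attr, attr=value}` markers, `[description]` brackets and a
  `!UnitClasses` section. Both round-trip exactly (names, descriptions,
  attributes, order), which the property suite checks on 50 seeded random
  schemas.
* **Case.** Matching is case-insensitive everywhere; storage preserves
  the schema's capitalization, which normalization restores. Unknown and
  extension segments are folded to lower case for determinism.
* **Normalization order.** Within every comma list (top level and each
  clause) tags sort case-insensitively; at the top level single tags
  precede groups, and groups sort by their serialized form. Clause order
  is preserved. The result is idempotent and injective across clause
  orderings, which makes it usable as a URI key.
* **Tildes only inside parentheses.** Every published use of the tilde is
  within a group; a top-level tilde is a syntax error, keeping the top
  level a pure comma list. An empty clause (`(/A ~ )`) is likewise
  rejected.
* **Misses vs forbidden values.** When a path fails to resolve, the
  deepest valid ancestor decides the diagnosis: a single numeric-looking
  remaining segment under a non-value, non-extensible node is
  `VALUE_FORBIDDEN` (a value hung where none belongs); anything else is
  `UNKNOWN_TAG`. Leaves are always extensible (extensions are how the
  vocabulary grows), so only interior nodes without `extensionAllowed`
  produce misses.
* **`childRequired`.** Read as a validation-time obligation: an exact
  match on such a node with no descendant segment is a `CHILD_REQUIRED`
  error. The required/recommended/unique checks apply per annotation
  string, the narrowest testable scope.
* **Remap vs translate.** `apply_remap()` matches whole tags
  case-insensitively — it corrects verbatim typos and is idempotent when
  no replacement is itself a key. `translate_tags()` matches by longest
  key prefix and re-appends the remainder, so a branch mapping carries all
  descendants; this is the mechanism for vocabulary-version translation
  (the concrete mapping table is the user's input).
* **Merging code- and instance-level tags.** The effective annotation of
  an event is the normalized union of the tags its code maps to and the
  tags recorded with the instance, with duplicate elements removed after
  normalization. When the two levels disagree (say, two different
  `/Event/Category` values) both are kept and the `unique` check is left
  to flag real conflicts.
* **`position` and `type` node attributes** are carried opaquely and
  round-tripped but drive no validation; no semantics are defined for
  them.
* **RDF mapping.** Events are typed by the URI of their percent-encoded
  normalized annotation. The instance-type predicate defaults to the
  standard `rdf:type`; the historical `rdfs:type` spelling is available
  via `type_spelling = "rdfs"`. Relations between co-occurring tags come
  from the fixed top-level rule table (Attribute describes
  Item/Participant/Event, Item/Participant performs Action, Paradigm
  describes Event, Sensory presentation presents Item) and are emitted
  only within a group — co-occurrence across groups carries no claim. One
  direction per pair is emitted by default; `inverse = TRUE` adds the
  mirrors. Nodes marked `predicateType = "property"` (identifying nodes
  such as `/Participant/ID`) export with an `isPropertyOf` relation
  rather than a subclass-style membership.

## What the generators emulate

`gen_schema(seed, depth, branching)` draws random vocabularies (bounded
depth, random extension and wildcard placement, the stock unit-class
registry) for round-trip and resolution testing. `gen_events(seed,
n_events, error_rate, schema)` emulates a tagged laboratory recording:
monotone event latencies about a second apart, a small pool of event
codes, and per-event annotations built from a category, a short label, a
description and a few stimulus tags — the shape of a traditional EEG
session with a handful of event types. A fraction `error_rate` of rows is
corrupted with exactly one fault each, drawn from the five classes a
curator actually meets (misspelled segment, non-numeric value, wrong
unit, dropped category, over-long label), and every fault is written to a
ledger. The validator must reproduce the ledger *exactly* — same codes,
rows, columns, tag texts — which the suite checks for seeds 1–20 at
`error_rate = 0.2` with 200 events per seed.

What the generator does **not** emulate: realistic EEG timing statistics,
correlated faults (real typos cluster by annotator), multi-study
repositories at archive scale, or annotation streams from virtual-world
simulators with hundreds of thousands of unique events. Passing the
ledger check therefore demonstrates bookkeeping correctness of the
validator on desk-scale tables, not robustness to every malformation a
wild spreadsheet can contain — syntax damage beyond the five classes is
covered separately by the parser's error tests.

The bundled fixture vocabulary (`fixture_schema()`, also shipped
serialized in `inst/extdata/`) is a curated ~100-node subset: the ten
top-level classes with enough depth to resolve every worked-example
annotation in `example_annotations()`. It stands in for the full
community vocabulary, which the schema readers ingest but the package
does not bundle.

## Numerical and degenerate-input choices

* Numbers accept decimal and scientific notation; value parsing never
  raises — validity is the caller's judgment, so a bad value yields one
  precise issue rather than an exception mid-table.
* Sample-to-second conversion is a single division, exact for integer
  samples and rates.
* Sorting uses radix order on the lower-cased key with the original
  string as tie-break, so normalization is locale-independent.
* Empty event-table cells mean "no tags" (not a syntax error); a ragged
  row is a structural error naming the row when reading, and a
  per-row issue (validation continues) when validating raw text.
* Epoch windows may start at negative times; clipping to recording bounds
  belongs to the caller, since no signal files are read.
* Problem sizes in the test suite — 50 schemas, 500 strings, 20×200
  events, 500 query cases — were chosen as the smallest rounds at which
  the property suites exercise every code path several times over.

## Known limitations

* One parenthesis level only; compound clauses require flattening.
* The query grammar is any/all over path prefixes — no negation, no
  nesting.
* No EEG signal I/O: epochs are abstract intervals keyed to latencies.
* The RDF export produces instance-level triples, not a full OWL
  ontology; reasoning and SPARQL are out of scope.
* The HED 1.0→2.0 translation mechanism is implemented
  (`translate_tags()`), but the authoritative mapping table is not
  shipped.

## A minimal session

```{r example}
schema <- fixture_schema()
ex <- example_annotations()

# parse and normalize the subject-predicate-object example
normalize_hed(ex[["man_ate_fish"]], schema)

# validate the chair/oddball annotation once a label is added
report <- validate_hed_string(
  paste0(ex[["chair_target"]], ", /Event/Label/chair"), schema)
nrow(report$errors)

# a seeded faulty table reproduces its injection ledger
g <- gen_events(11, n_events = 30, error_rate = 0.2, schema = schema)
r <- validate_event_table(g$text, 1, 3, FALSE, schema)
nrow(r$errors) + nrow(r$warnings) == nrow(g$ledger)
```
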