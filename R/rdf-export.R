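# RDF triple export: event instances typed by the URI of their normalized
# annotation, rdfs:label / rdfs:comment from /Event/Label and
# /Event/Description, co-occurrence relations between top-level classes
# within a tag group, and subject-predicate-object statements from
# three-clause tilde groups.

.rdf_ns <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#"
)

#' The implied relations between top-level classes
#'
#' Each row relates a pair of top-level vocabulary classes whose tags
#' co-occur in a group: Item/Participant/Event are described by Attribute,
#' Action is performed by Item/Participant, Event is described by Paradigm,
#' and Sensory presentation presents Item.  Rows with `canonical = TRUE`
#' are emitted by default; the remaining rows are the inverse directions,
#' emitted when inverse emission is enabled.
#'
#' @return Data frame with columns `from`, `relation`, `to`, `canonical`.
#' @export
hed_relation_rules <- function() {
  rule <- function(from, relation, to, canonical) {
    expand.grid(from = from, relation = relation, to = to,
                canonical = canonical, stringsAsFactors = FALSE)
  }
  rbind(
    rule(c("Item", "Participant", "Event"), "isDescribedBy", "Attribute", TRUE),
    rule("Attribute", "describes", c("Item", "Participant", "Event"), FALSE),
    rule("Action", "isPerformedBy", c("Item", "Participant"), TRUE),
    rule(c("Item", "Participant"), "performs", "Action", FALSE),
    rule("Event", "isDescribedBy", "Paradigm", TRUE),
    rule("Paradigm", "describes", "Event", FALSE),
    rule("Sensory presentation", "presents", "Item", TRUE),
    rule("Item", "isPresentedBy", "Sensory presentation", FALSE)
  )
}

pct_encode <- function(x) utils::URLencode(x, reserved = TRUE)

#' URI of a normalized HED string
#'
#' The URI is `base` followed by the percent-encoded normalized text, so
#' annotations equal up to comma-list ordering share a URI while groups
#' with reordered clauses (different subject-predicate-object meaning) do
#' not.  `utils::URLdecode()` recovers the normalized text.
#'
#' @param hs A `hed_string` or annotation text.
#' @param base URI prefix text.
#' @param schema Optional schema for canonical capitalization.
#' @return URI text.
#' @export
hed_string_uri <- function(hs, base, schema = NULL) {
  paste0(base, pct_encode(normalize_hed(hs, schema)))
}

hed_tag_uri <- function(tag, base, schema = NULL) {
  paste0(base, "HEDTag/", pct_encode(canonical_tag_text(tag, schema)))
}

make_triple <- function(subject, predicate, object, literal = FALSE) {
  data.frame(subject = subject, predicate = predicate, object = object,
             literal = literal, stringsAsFactors = FALSE)
}

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), literal = logical(),
             stringsAsFactors = FALSE)
}

top_class <- function(tag, schema = NULL) {
  seg <- tag$segments[1]
  if (!is.null(schema)) {
    e <- schema$index[[tolower(paste0("/", seg))]]
    if (!is.null(e)) return(e$name)
  }
  seg
}

# Predicate URIs.  The instance-type predicate defaults to the standard
# rdf:type; type_spelling = "rdfs" reproduces the literal "rdfs:type"
# spelling instead.
type_predicate <- function(as_type, type_spelling) {
  if (as_type) return(paste0(.rdf_ns[["rdfs"]], "subClassOf"))
  if (type_spelling == "rdfs") paste0(.rdf_ns[["rdfs"]], "type")
  else paste0(.rdf_ns[["rdf"]], "type")
}

#' Emit RDF triples for an annotated event
#'
#' Emits: the event's type statement linking it to the URI of its
#' normalized annotation (`rdfs:subClassOf` instead when `as_type` marks an
#' event type rather than an instance); an `rdfs:label` literal when an
#' `/Event/Label` value is present and an `rdfs:comment` literal for
#' `/Event/Description`; a membership statement for every tag (tags on
#' nodes with `predicateType = "property"` use the vocabulary's
#' `isPropertyOf` relation instead); for each group, one relation triple
#' per ordered pair of member tags whose top-level classes satisfy a rule
#' of [hed_relation_rules()] (inverse directions only when `inverse =
#' TRUE`); and for each three-clause tilde group one statement whose
#' subject, predicate and object are the URIs of the clauses.  Relations
#' are never emitted across groups.
#'
#' @param event_id URI of the event instance (or type).
#' @param hs A `hed_string` or annotation text.
#' @param schema A `hed_schema`.
#' @param base URI base, e.g. `"http://hedtags.org/schema/v2/"`; the
#'   annotation URI lives under `<base>HEDString/` and tag URIs under
#'   `<base>HEDTag/`.
#' @param as_type `FALSE` (default) for an event instance, `TRUE` for an
#'   event type.
#' @param inverse Also emit the inverse relation rows.
#' @param type_spelling `"rdf"` (standard `rdf:type`) or `"rdfs"`.
#' @return Data frame of triples (`subject`, `predicate`, `object`,
#'   `literal`), deterministic given normalized input.
#' @export
instance_triples <- function(event_id, hs, schema,
                             base = "http://hedtags.org/schema/v2/",
                             as_type = FALSE, inverse = FALSE,
                             type_spelling = c("rdf", "rdfs")) {
  type_spelling <- match.arg(type_spelling)
  if (is.character(hs)) hs <- parse_hed(hs)
  H <- hed_string_uri(hs, paste0(base, "HEDString/"), schema)
  out <- list(make_triple(event_id, type_predicate(as_type, type_spelling), H))

  tags <- flatten_hed_tags(hs)
  for (tag in tags) {
    m <- hed_locate(schema, tag)
    if (m$kind == "valueMatch" && !is.na(m$path)) {
      if (tolower(m$path) == "/event/label") {
        out <- c(out, list(make_triple(
          H, paste0(.rdf_ns[["rdfs"]], "label"), m$value, literal = TRUE)))
      }
      if (tolower(m$path) == "/event/description") {
        out <- c(out, list(make_triple(
          H, paste0(.rdf_ns[["rdfs"]], "comment"), m$value, literal = TRUE)))
      }
    }
    turi <- hed_tag_uri(tag, base, schema)
    node_attrs <- if (m$kind == "valueMatch" || m$kind == "exact") m$attrs
                  else list()
    if (identical(node_attrs$predicateType, "property")) {
      out <- c(out, list(make_triple(turi, paste0(base, "isPropertyOf"), H)))
    } else {
      out <- c(out, list(make_triple(H, paste0(base, "hasTag"), turi)))
    }
  }

  rules <- hed_relation_rules()
  if (!inverse) rules <- rules[rules$canonical, , drop = FALSE]
  for (el in hs$elements) {
    if (!is_hed_group(el)) next
    gtags <- unlist(el$clauses, recursive = FALSE)
    if (length(gtags) > 1L) {
      classes <- vapply(gtags, top_class, "", schema = schema)
      for (i in seq_along(gtags)) {
        for (j in seq_along(gtags)) {
          if (i == j) next
          hit <- rules$relation[rules$from == classes[i] &
                                  rules$to == classes[j]]
          for (rel in hit) {
            out <- c(out, list(make_triple(
              hed_tag_uri(gtags[[i]], base, schema), paste0(base, rel),
              hed_tag_uri(gtags[[j]], base, schema))))
          }
        }
      }
    }
    if (length(el$clauses) == 3L) {
      curi <- vapply(el$clauses, function(cl) {
        txt <- paste(vapply(cl, format, ""), collapse = ", ")
        paste0(base, "HEDClause/", pct_encode(normalize_hed(txt, schema)))
      }, "")
      out <- c(out, list(make_triple(curi[1], curi[2], curi[3])))
    }
  }
  triples <- do.call(rbind, out)
  rownames(triples) <- NULL
  unique(triples)
}

#' Emit triples for every tagged event of a table
#'
#' Event URIs are `<base>EventInstance/<n>` numbered in table order.
#'
#' @param table A `hed_event_table`.
#' @inheritParams instance_triples
#' @return Data frame of triples.
#' @export
event_table_triples <- function(table, schema,
                                base = "http://hedtags.org/schema/v2/",
                                inverse = FALSE,
                                type_spelling = c("rdf", "rdfs")) {
  type_spelling <- match.arg(type_spelling)
  out <- list(empty_triples())
  for (i in seq_along(table$records)) {
    hs <- effective_tags(table$records[[i]], schema)
    if (is.null(hs)) next
    out <- c(out, list(instance_triples(
      paste0(base, "EventInstance/", i), hs, schema, base,
      inverse = inverse, type_spelling = type_spelling)))
  }
  triples <- do.call(rbind, out)
  rownames(triples) <- NULL
  triples
}

escape_nt_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

#' Serialize triples as N-Triples or Turtle
#'
#' @param triples Triple data frame from [instance_triples()] or
#'   [event_table_triples()].
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The serialized text, invisibly when written to a file.
#' @export
write_ntriples <- function(triples, path = NULL) {
  obj <- ifelse(triples$literal,
                paste0("\"", escape_nt_literal(triples$object), "\""),
                paste0("<", triples$object, ">"))
  lines <- sprintf("<%s> <%s> %s .", triples$subject, triples$predicate, obj)
  text <- paste0(paste(lines, collapse = "\n"),
                 if (length(lines)) "\n" else "")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}

#' @rdname write_ntriples
#' @export
write_turtle <- function(triples, path = NULL) {
  shorten <- function(uri) {
    for (pfx in names(.rdf_ns)) {
      ns <- .rdf_ns[[pfx]]
      hit <- startsWith(uri, ns)
      uri[hit] <- paste0(pfx, ":", substring(uri[hit], nchar(ns) + 1L))
    }
    ifelse(grepl("^(rdf|rdfs):", uri), uri, paste0("<", uri, ">"))
  }
  obj <- ifelse(triples$literal,
                paste0("\"", escape_nt_literal(triples$object), "\""),
                shorten(triples$object))
  lines <- c(sprintf("@prefix %s: <%s> .", names(.rdf_ns), unname(.rdf_ns)),
             "",
             sprintf("%s %s %s .", shorten(triples$subject),
                     shorten(triples$predicate), obj))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}
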