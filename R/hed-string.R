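# HED annotation strings: comma-separated tags and one-level parenthesized
# groups whose 1-3 tilde-separated clauses form subject-predicate-object
# statements.

make_hed_tag <- function(text, value = NULL) {
  segments <- split_tag_path(text)
  structure(list(text = join_tag_path(segments), segments = segments,
                 value = value),
            class = "hed_tag")
}

#' Is an element a tag group?
#' @param x A parsed element.
#' @return Logical.
#' @export
is_hed_group <- function(x) inherits(x, "hed_group")

#' Parse a HED annotation string
#'
#' Commas separate elements; `(` ... `)` delimits a group (one level only);
#' `~` splits a group into at most three clauses, each a comma list of tags;
#' whitespace around delimiters is ignored.
#'
#' @param text Non-empty annotation text.
#' @return An object of class `hed_string` with fields `elements` (each a
#'   `hed_tag` or `hed_group`) and `source`.
#' @details Syntax errors (unbalanced or nested parentheses, more than three
#'   tilde clauses, a tilde outside a group, empty elements) raise a
#'   condition of class `hed_syntax_error` whose message reports a 1-based
#'   character position within the input.
#' @export
parse_hed <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trim(text))) {
    stop_hed("hed_usage_error", "annotation text must be a non-empty string")
  }
  syntax <- function(msg, pos) {
    stop_hed("hed_syntax_error",
             sprintf("%s (at position %d)", msg, pos), position = pos)
  }
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  depth <- 0L
  elements <- list()
  buf_start <- 1L        # element start position
  group_open <- NA_integer_

  mk_tag <- function(s, e) {
    piece <- trim(substr(text, s, e))
    if (!nzchar(piece)) syntax("empty tag", s)
    make_hed_tag(piece)
  }
  parse_group <- function(open, close) {
    inner <- substr(text, open + 1L, close - 1L)
    tpos <- c(open, open + which(strsplit(inner, "")[[1]] == "~"), close)
    if (length(tpos) - 2L + 1L > 3L) {
      syntax("a group may contain at most 3 tilde clauses", tpos[5])
    }
    clauses <- list()
    for (ci in seq_len(length(tpos) - 1L)) {
      cs <- tpos[ci] + 1L
      ce <- tpos[ci + 1L] - 1L
      ctext <- substr(text, cs, ce)
      if (!nzchar(trim(ctext))) syntax("empty clause in group", cs)
      cchars <- strsplit(ctext, "")[[1]]
      commas <- which(cchars == ",")
      bounds <- c(cs - 1L, cs - 1L + commas, ce + 1L)
      tags <- list()
      for (ti in seq_len(length(bounds) - 1L)) {
        tags[[length(tags) + 1L]] <- mk_tag(bounds[ti] + 1L, bounds[ti + 1L] - 1L)
      }
      clauses[[ci]] <- tags
    }
    structure(list(clauses = clauses), class = "hed_group")
  }
  close_element <- function(s, e) {
    piece_raw <- substr(text, s, e)
    piece <- trim(piece_raw)
    if (!nzchar(piece)) syntax("empty element between commas", s)
    pchars <- strsplit(piece_raw, "")[[1]]
    opens <- s - 1L + which(pchars == "(")
    closes <- s - 1L + which(pchars == ")")
    if (length(opens)) {
      if (!startsWith(piece, "(")) syntax("unexpected '(' inside element", opens[1])
      if (!endsWith(piece, ")")) {
        syntax("text after closing parenthesis", closes[length(closes)])
      }
      elements[[length(elements) + 1L]] <<-
        parse_group(opens[1], closes[length(closes)])
    } else {
      elements[[length(elements) + 1L]] <<- make_hed_tag(piece)
    }
  }

  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
      if (depth > 1L) syntax("nesting limited to one level", i)
      group_open <- i
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) syntax("unbalanced ')'", i)
    } else if (ch == "~" && depth == 0L) {
      syntax("'~' outside a group", i)
    } else if (ch == "," && depth == 0L) {
      close_element(buf_start, i - 1L)
      buf_start <- i + 1L
    }
  }
  if (depth != 0L) syntax("unbalanced '('", group_open)
  close_element(buf_start, n)
  structure(list(elements = elements, source = text), class = "hed_string")
}

#' @export
format.hed_tag <- function(x, ...) x$text

#' @export
format.hed_group <- function(x, ...) {
  clause_txt <- vapply(x$clauses, function(tags) {
    paste(vapply(tags, format, ""), collapse = ", ")
  }, "")
  paste0("(", paste(clause_txt, collapse = " ~ "), ")")
}

#' @export
format.hed_string <- function(x, ...) serialize_hed(x)

#' Serialize a parsed HED string
#'
#' Canonical spacing: `", "` between elements and tags, `" ~ "` between
#' clauses, no space inside parenthesis edges.  `parse_hed(serialize_hed(x))`
#' reproduces `x`.
#'
#' @param hs A `hed_string` (or a single `hed_tag`/`hed_group`).
#' @return Annotation text.
#' @export
serialize_hed <- function(hs) {
  if (inherits(hs, c("hed_tag", "hed_group"))) return(format(hs))
  paste(vapply(hs$elements, format, ""), collapse = ", ")
}

#' @export
print.hed_string <- function(x, ...) {
  cat(serialize_hed(x), "\n")
  invisible(x)
}

#' @export
print.hed_tag <- function(x, ...) { cat(x$text, "\n"); invisible(x) }

#' @export
print.hed_group <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Canonical capitalization for one tag: schema capitalization for matched
# segments, value text preserved for value positions, lower-case fold for
# extension segments and unknown tags.
canonical_tag_text <- function(tag, schema = NULL) {
  if (is.null(schema)) return(tolower(tag$text))
  m <- hed_locate(schema, tag)
  switch(m$kind,
    exact = m$path,
    valueMatch = paste0(m$path, "/", m$value),
    extension = paste0(m$path, "/",
                       paste(tolower(m$extension_segments), collapse = "/")),
    tolower(tag$text))
}

#' Normalize a HED string to a unique text representation
#'
#' Produces a deterministic canonical text: tags are case-folded to the
#' schema's capitalization when a schema is given (unknown tags are folded
#' to lower case), every comma list (the top level and each clause) is
#' sorted case-insensitively, top-level single tags precede groups, and
#' clause order inside groups is preserved because it carries
#' subject-predicate-object meaning.  The operation is idempotent.
#'
#' @param hs A `hed_string` or annotation text.
#' @param schema Optional `hed_schema` used for canonical capitalization.
#' @return Normalized annotation text.
#' @export
normalize_hed <- function(hs, schema = NULL) {
  if (is.character(hs)) hs <- parse_hed(hs)
  norm_tags <- function(tags) {
    txt <- vapply(tags, canonical_tag_text, "", schema = schema)
    txt[ci_order(txt)]
  }
  singles <- character()
  groups <- character()
  for (el in hs$elements) {
    if (is_hed_group(el)) {
      clause_txt <- vapply(el$clauses, function(tags) {
        paste(norm_tags(tags), collapse = ", ")
      }, "")
      groups <- c(groups, paste0("(", paste(clause_txt, collapse = " ~ "), ")"))
    } else {
      singles <- c(singles, canonical_tag_text(el, schema))
    }
  }
  singles <- singles[ci_order(singles)]
  groups <- groups[ci_order(groups)]
  paste(c(singles, groups), collapse = ", ")
}

#' Substitute a value into a `#` wildcard template
#'
#' @param template Tag path whose final segment is `#`.
#' @param value Replacement text; recorded in the returned tag's `value`
#'   field.  An empty value yields an empty final segment, left for
#'   validation to flag.
#' @return A `hed_tag`.
#' @export
substitute_value <- function(template, value) {
  segs <- split_tag_path(template)
  if (length(segs) == 0L || segs[length(segs)] != "#") {
    stop_hed("hed_usage_error", "template must end in '#'")
  }
  segs[length(segs)] <- value
  structure(list(text = join_tag_path(segs), segments = segs[nzchar(segs)],
                 value = value),
            class = "hed_tag")
}

#' Parse the value part of a value-taking tag
#'
#' With a unit class, accepts `"<number> <unit>"` (single space, unit among
#' the allowed units), a bare number (the default unit applies), or
#' `"<symbol><number>"` for single-symbol units such as `$`.  With
#' `numeric_required` and no unit class, only a bare number parses.  The
#' function never raises; validity is judged by the caller.
#'
#' @param value Non-empty value text.
#' @param unit_class Optional `hed_unit_class`.
#' @param numeric_required Whether a numeric value is required.
#' @return List with fields `ok`, `number`, `unit` and `reason`
#'   (`NA`, `"not_numeric"`, or `"bad_unit"`).
#' @export
parse_hed_value <- function(value, unit_class = NULL, numeric_required = FALSE) {
  out <- list(ok = TRUE, number = NA_real_, unit = NA_character_,
              reason = NA_character_)
  v <- trim(value)
  if (!is.null(unit_class)) {
    if (is_number_text(v)) {
      out$number <- as.numeric(v)
      out$unit <- unit_class$default
      return(out)
    }
    for (u in unit_class$units[nchar(unit_class$units) == 1L &
                               !grepl("[[:alnum:]]", unit_class$units)]) {
      if (startsWith(v, u) && is_number_text(substring(v, nchar(u) + 1L))) {
        out$number <- as.numeric(substring(v, nchar(u) + 1L))
        out$unit <- u
        return(out)
      }
    }
    sp <- regexpr(" ", v, fixed = TRUE)
    if (sp > 0L) {
      num <- substr(v, 1L, sp - 1L)
      unit <- substring(v, sp + 1L)
      if (is_number_text(num)) {
        out$number <- as.numeric(num)
        out$unit <- unit
        if (!unit %in% unit_class$units) {
          out$ok <- FALSE
          out$reason <- "bad_unit"
        }
        return(out)
      }
    }
    out$ok <- FALSE
    out$reason <- "not_numeric"
    return(out)
  }
  if (numeric_required) {
    if (is_number_text(v)) {
      out$number <- as.numeric(v)
    } else {
      out$ok <- FALSE
      out$reason <- "not_numeric"
    }
  }
  out
}

# Flatten all tags of a hed_string: top level plus all groups and clauses.
flatten_hed_tags <- function(hs) {
  out <- list()
  for (el in hs$elements) {
    if (is_hed_group(el)) {
      for (cl in el$clauses) out <- c(out, cl)
    } else {
      out <- c(out, list(el))
    }
  }
  out
}
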