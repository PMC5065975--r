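# Schema-driven validation of HED strings and event tables, plus the
# remap/translate correction mechanics.

.issue_codes <- c("UNKNOWN_TAG", "REQUIRED_MISSING", "RECOMMENDED_MISSING",
                  "UNIT_INVALID", "NOT_NUMERIC", "VALUE_FORBIDDEN",
                  "UNIQUE_VIOLATED", "CHILD_REQUIRED", "LABEL_TOO_LONG",
                  "SYNTAX", "EXTENSION")

# /Event/Label values shorter than this many characters are accepted; at
# this length and beyond a warning is emitted.
.label_max_chars <- 20L

make_issue <- function(severity, code, message, tag = "", row = NA_integer_,
                       column = NA_integer_) {
  stopifnot(code %in% .issue_codes)
  data.frame(severity = severity, code = code, message = message, tag = tag,
             row = as.integer(row), column = as.integer(column),
             stringsAsFactors = FALSE)
}

empty_issues <- function() {
  data.frame(severity = character(), code = character(), message = character(),
             tag = character(), row = integer(), column = integer(),
             stringsAsFactors = FALSE)
}

bind_issues <- function(lst) {
  lst <- lst[vapply(lst, NROW, 0L) > 0L]
  if (!length(lst)) empty_issues() else do.call(rbind, lst)
}

#' Build a validation report from a set of issues
#'
#' A report partitions issues into errors, warnings and extensions by
#' severity, and derives `remap`: the sorted unique texts of tags flagged
#' `UNKNOWN_TAG`, the starting point for building a correction table.
#'
#' @param issues Issue data frame.
#' @return An object of class `hed_report` with fields `errors`, `warnings`,
#'   `extensions` and `remap`.
#' @export
hed_report <- function(issues = empty_issues()) {
  rownames(issues) <- NULL
  unknown <- issues$tag[issues$code == "UNKNOWN_TAG" &
                          issues$severity == "error"]
  structure(list(
    errors = issues[issues$severity == "error", , drop = FALSE],
    warnings = issues[issues$severity == "warning", , drop = FALSE],
    extensions = issues[issues$severity == "extension", , drop = FALSE],
    remap = sort(unique(unknown))
  ), class = "hed_report")
}

#' @export
print.hed_report <- function(x, ...) {
  section <- function(title, df) {
    cat(sprintf("%s (%d)\n", title, nrow(df)))
    if (nrow(df)) {
      for (i in seq_len(nrow(df))) {
        loc <- if (!is.na(df$row[i]))
          sprintf(" [row %d%s]", df$row[i],
                  if (!is.na(df$column[i])) sprintf(", col %d", df$column[i]) else "")
          else ""
        cat(sprintf("  %s: %s%s\n", df$code[i], df$message[i], loc))
      }
    }
  }
  section("Errors", x$errors)
  section("Warnings", x$warnings)
  section("Extensions", x$extensions)
  cat(sprintf("Remap (%d)\n", length(x$remap)))
  for (t in x$remap) cat("  ", t, "\n", sep = "")
  invisible(x)
}

report_issues <- function(report) {
  bind_issues(list(report$errors, report$warnings, report$extensions))
}

#' Validate a single tag against a schema
#'
#' Emits `UNKNOWN_TAG` for unresolvable paths, an `EXTENSION` record for
#' user extensions in allowed places (leaves, or nodes with
#' `extensionAllowed`), `NOT_NUMERIC` and `UNIT_INVALID` for bad values
#' under `isNumeric`/unit-classed wildcards, `VALUE_FORBIDDEN` when a
#' numeric value hangs off a node that neither takes values nor allows
#' extension, `CHILD_REQUIRED` when a `childRequired` node appears with no
#' descendant segment, and a `LABEL_TOO_LONG` warning for `/Event/Label`
#' values of 20 or more characters.
#'
#' @param tag A `hed_tag` or tag text.
#' @param schema A `hed_schema`.
#' @return Issue data frame (possibly empty).
#' @export
validate_tag <- function(tag, schema) {
  if (is.character(tag)) tag <- make_hed_tag(tag)
  m <- hed_locate(schema, tag)
  issues <- list()
  if (m$kind == "miss") {
    if (length(m$extension_segments) == 1L && m$matched_depth >= 1L &&
        is_number_text(m$extension_segments[1])) {
      return(make_issue("error", "VALUE_FORBIDDEN",
                        sprintf("node %s does not take values", m$path),
                        tag$text))
    }
    return(make_issue("error", "UNKNOWN_TAG",
                      sprintf("tag not in schema: %s", tag$text), tag$text))
  }
  if (m$kind == "extension") {
    return(make_issue("extension", "EXTENSION",
                      sprintf("extension of %s: %s", m$path, tag$text),
                      tag$text))
  }
  if (m$kind == "exact") {
    if (isTRUE(m$attrs$childRequired)) {
      issues <- c(issues, list(make_issue(
        "error", "CHILD_REQUIRED",
        sprintf("%s requires a child tag or value", m$path), tag$text)))
    }
  } else { # valueMatch
    ha <- m$hash_attrs %||% list()
    uc <- if (!is.null(ha$unitClass)) schema$unit_classes[[ha$unitClass]]
    pv <- parse_hed_value(m$value, unit_class = uc,
                          numeric_required = isTRUE(ha$isNumeric))
    if (!pv$ok) {
      if (identical(pv$reason, "bad_unit")) {
        issues <- c(issues, list(make_issue(
          "error", "UNIT_INVALID",
          sprintf("unit '%s' not allowed for unit class '%s' in %s",
                  pv$unit, ha$unitClass, tag$text), tag$text)))
      } else {
        issues <- c(issues, list(make_issue(
          "error", "NOT_NUMERIC",
          sprintf("value '%s' of %s is not numeric", m$value, tag$text),
          tag$text)))
      }
    }
    if (tolower(m$path) == "/event/label" &&
        nchar(m$value) >= .label_max_chars) {
      issues <- c(issues, list(make_issue(
        "warning", "LABEL_TOO_LONG",
        sprintf("label '%s' has %d characters; labels should be shorter than %d",
                m$value, nchar(m$value), .label_max_chars), tag$text)))
    }
  }
  bind_issues(issues)
}

# Schema paths carrying a given flag.
flagged_paths <- function(schema, flag) {
  hits <- Filter(function(e) isTRUE(e$attrs[[flag]]), schema$index)
  vapply(hits, `[[`, "", "path", USE.NAMES = FALSE)
}

tag_descends_from <- function(tag, path_lower) {
  tl <- tolower(tag$text)
  tl == path_lower || startsWith(tl, paste0(path_lower, "/"))
}

#' Validate a full annotation string
#'
#' Runs [validate_tag()] on every tag (top level and inside groups) and adds
#' string-level checks: `REQUIRED_MISSING` when no tag descends from a
#' required node (the fixture schema requires `/Event/Category` and
#' `/Event/Label`), `RECOMMENDED_MISSING` (warning) for recommended nodes,
#' and `UNIQUE_VIOLATED` when a unique-attributed node prefixes more than
#' one tag in the string.
#'
#' @param hs A `hed_string` or annotation text.
#' @param schema A `hed_schema`.
#' @return A `hed_report`.
#' @export
validate_hed_string <- function(hs, schema) {
  if (is.character(hs)) hs <- parse_hed(hs)
  tags <- flatten_hed_tags(hs)
  issues <- lapply(tags, validate_tag, schema = schema)
  issues <- c(issues, list(string_level_issues(tags, schema)))
  hed_report(bind_issues(issues))
}

string_level_issues <- function(tags, schema) {
  issues <- list()
  count_under <- function(path) {
    sum(vapply(tags, tag_descends_from, NA, path_lower = tolower(path)))
  }
  for (p in flagged_paths(schema, "required")) {
    if (count_under(p) == 0L) {
      issues <- c(issues, list(make_issue(
        "error", "REQUIRED_MISSING",
        sprintf("annotation lacks a required %s tag", p), p)))
    }
  }
  for (p in flagged_paths(schema, "recommended")) {
    if (count_under(p) == 0L) {
      issues <- c(issues, list(make_issue(
        "warning", "RECOMMENDED_MISSING",
        sprintf("annotation lacks a recommended %s tag", p), p)))
    }
  }
  for (p in flagged_paths(schema, "unique")) {
    if (count_under(p) > 1L) {
      issues <- c(issues, list(make_issue(
        "error", "UNIQUE_VIOLATED",
        sprintf("more than one tag under unique node %s", p), p)))
    }
  }
  bind_issues(issues)
}

#' Validate the tag columns of an event table
#'
#' Each tag-column cell of every event row is parsed and validated; the
#' string-level checks run on the event's full annotation (all tag columns
#' of the row concatenated).  Issues carry 1-based file row numbers (a
#' header row counts as row 1 when present) and column numbers.  The
#' report's `remap` aggregates unique invalid tags over the whole table,
#' sorted.
#'
#' @param x An event table from [read_events_tsv()], raw TSV text, or a file
#'   path.
#' @param id_column 1-based identifier column (used when reading raw text).
#' @param tag_columns 1-based tag column indices.
#' @param has_header Whether the first row is a header.
#' @param schema A `hed_schema`.
#' @return A `hed_report`.  A row missing a referenced column yields a
#'   structural `SYNTAX` error issue for that row and validation continues.
#' @export
validate_event_table <- function(x, id_column = 1L, tag_columns = 2L,
                                 has_header = FALSE, schema) {
  if (inherits(x, "hed_event_table")) {
    tab <- x
    id_column <- tab$id_column
    tag_columns <- tab$tag_columns
    has_header <- !is.null(tab$header)
    cells <- lapply(tab$records, `[[`, "raw")
  } else {
    lines <- read_lines_any(x)
    cells <- lapply(lines, split_fields)
    if (has_header && length(cells)) cells <- cells[-1]
  }
  offset <- if (has_header) 1L else 0L
  issues <- list()
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    file_row <- i + offset
    if (length(row) < max(c(id_column, tag_columns))) {
      issues <- c(issues, list(make_issue(
        "error", "SYNTAX",
        sprintf("row %d has %d column(s); %d required", file_row, length(row),
                max(c(id_column, tag_columns))), "", file_row)))
      next
    }
    row_tags <- list()
    for (col in tag_columns) {
      cell <- trim(row[col])
      if (!nzchar(cell)) next
      hs <- tryCatch(parse_hed(cell), error = function(e) e)
      if (inherits(hs, "error")) {
        issues <- c(issues, list(make_issue(
          "error", "SYNTAX", conditionMessage(hs), cell, file_row, col)))
        next
      }
      for (tag in flatten_hed_tags(hs)) {
        ti <- validate_tag(tag, schema)
        if (nrow(ti)) {
          ti$row <- as.integer(file_row)
          ti$column <- as.integer(col)
          issues <- c(issues, list(ti))
        }
      }
      row_tags <- c(row_tags, flatten_hed_tags(hs))
    }
    si <- string_level_issues(row_tags, schema)
    if (nrow(si)) {
      si$row <- as.integer(file_row)
      issues <- c(issues, list(si))
    }
  }
  hed_report(bind_issues(issues))
}

#' Build a remap table
#'
#' @param keys Invalid tag texts (matched case-insensitively as whole tags).
#' @param values Replacement tag texts, parallel to `keys`.
#' @return An object of class `hed_remap`.
#' @export
hed_remap <- function(keys = character(), values = character()) {
  stopifnot(length(keys) == length(values))
  keys <- vapply(keys, function(k) join_tag_path(split_tag_path(k)), "")
  values <- vapply(values, function(v) join_tag_path(split_tag_path(v)), "")
  if (anyDuplicated(tolower(keys))) {
    stop_hed("hed_usage_error", "duplicate keys in remap table")
  }
  structure(list(keys = unname(keys), values = unname(values)),
            class = "hed_remap")
}

#' Read / write two-column TSV remap tables
#'
#' @param x Remap TSV text or file path (columns: invalid tag, replacement).
#' @return [load_remap()] returns a `hed_remap`; [save_remap()] returns TSV
#'   text.
#' @export
load_remap <- function(x) {
  lines <- read_lines_any(x)
  lines <- lines[nzchar(trim(lines)) & !startsWith(lines, "#")]
  parts <- lapply(lines, split_fields)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) {
    stop_hed("hed_parse_error",
             sprintf("remap line %d lacks a replacement column", bad[1]))
  }
  hed_remap(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' @param remap A `hed_remap`.
#' @rdname load_remap
#' @export
save_remap <- function(remap) {
  paste0(paste(remap$keys, remap$values, sep = "\t", collapse = "\n"), "\n")
}

remap_one_tag <- function(tag, remap, prefix = FALSE) {
  if (!prefix) {
    hit <- match(tolower(tag$text), tolower(remap$keys))
    if (!is.na(hit)) return(make_hed_tag(remap$values[hit], value = tag$value))
    return(tag)
  }
  key_segs <- lapply(remap$keys, function(k) tolower(split_tag_path(k)))
  tl <- tolower(tag$segments)
  best <- 0L
  best_i <- NA_integer_
  for (i in seq_along(key_segs)) {
    ks <- key_segs[[i]]
    if (length(ks) <= length(tl) && length(ks) > best &&
        identical(ks, tl[seq_along(ks)])) {
      best <- length(ks)
      best_i <- i
    }
  }
  if (is.na(best_i)) return(tag)
  rest <- tag$segments[-seq_len(best)]
  make_hed_tag(paste(c(remap$values[best_i], rest), collapse = "/"))
}

remap_hed_string <- function(hs, remap, prefix = FALSE) {
  map_tags <- function(tags) lapply(tags, remap_one_tag, remap = remap,
                                    prefix = prefix)
  hs$elements <- lapply(hs$elements, function(el) {
    if (is_hed_group(el)) {
      el$clauses <- lapply(el$clauses, map_tags)
      el
    } else {
      remap_one_tag(el, remap, prefix)
    }
  })
  hs
}

remap_cells <- function(cells, tag_columns, remap, prefix = FALSE) {
  lapply(cells, function(row) {
    for (col in tag_columns) {
      if (col > length(row)) next
      cell <- trim(row[col])
      if (!nzchar(cell)) next
      hs <- tryCatch(parse_hed(cell), error = function(e) NULL)
      if (is.null(hs)) next
      row[col] <- serialize_hed(remap_hed_string(hs, remap, prefix))
    }
    row
  })
}

#' Apply a remap table to an event table
#'
#' Every occurrence of a key tag (case-insensitive whole-tag match) in the
#' tag columns is replaced by its correction; other tags are untouched.  The
#' operation is idempotent when no replacement is itself a key.
#'
#' @param x An event table ([read_events_tsv()]), raw TSV text or path.
#' @param remap A `hed_remap`.
#' @param tag_columns 1-based tag columns (taken from the table when `x` is
#'   one).
#' @param has_header Whether the first row is a header (raw input only).
#' @return The corrected object, same form as the input (event table in,
#'   event table out; text in, text out).
#' @export
apply_remap <- function(x, remap, tag_columns = 2L, has_header = FALSE) {
  if (inherits(x, "hed_event_table")) {
    cells <- lapply(x$records, `[[`, "raw")
    cells <- remap_cells(cells, x$tag_columns, remap)
    lines <- vapply(cells, paste, "", collapse = "\t")
    if (!is.null(x$header)) {
      lines <- c(paste(x$header, collapse = "\t"), lines)
    }
    return(read_events_tsv(if (length(lines)) lines else "",
                           id_column = x$id_column,
                           tag_columns = x$tag_columns,
                           has_header = !is.null(x$header),
                           code_column = x$code_column))
  }
  lines <- read_lines_any(x)
  header <- NULL
  if (has_header && length(lines)) {
    header <- lines[1]
    lines <- lines[-1]
  }
  cells <- lapply(lines, split_fields)
  cells <- remap_cells(cells, tag_columns, remap)
  out <- vapply(cells, paste, "", collapse = "\t")
  paste0(paste(c(header, out), collapse = "\n"), "\n")
}

#' Translate tags between vocabulary versions by longest prefix
#'
#' Unlike [apply_remap()], which corrects whole tags verbatim, translation
#' matches by longest key prefix and re-appends the remaining segments, so a
#' mapping for a branch carries all its descendants.
#'
#' @param x A `hed_string`, `hed_tag`, tag text, or character vector of tag
#'   texts.
#' @param mapping A `hed_remap` whose keys are old-vocabulary prefixes.
#' @return Translated object of the same form.
#' @export
translate_tags <- function(x, mapping) {
  if (inherits(x, "hed_tag")) return(remap_one_tag(x, mapping, prefix = TRUE))
  if (inherits(x, "hed_string")) {
    return(remap_hed_string(x, mapping, prefix = TRUE))
  }
  vapply(x, function(t) {
    remap_one_tag(make_hed_tag(t), mapping, prefix = TRUE)$text
  }, "", USE.NAMES = FALSE)
}
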