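# Event tables and tag maps: tab-separated files in which each line has an
# identifier column (an event code, or a latency in the recording) plus one
# or more columns of HED tags, and code->tags map files applied to them.

make_event_record <- function(raw, id_column, tag_columns,
                              latency_unit = "seconds", sampling_rate = NULL,
                              code_column = NULL) {
  id <- trim(raw[id_column])
  code <- NA_character_
  latency <- NA_real_
  if (is_number_text(id)) {
    latency <- as.numeric(id)
    if (latency_unit == "samples") latency <- latency / sampling_rate
  } else {
    code <- id
  }
  if (!is.null(code_column)) code <- trim(raw[code_column])
  cellparts <- character()
  for (col in tag_columns) {
    cell <- trim(raw[col])
    if (nzchar(cell)) cellparts <- c(cellparts, cell)
  }
  instance <- if (length(cellparts))
    parse_hed(paste(cellparts, collapse = ", ")) else NULL
  structure(list(code = code, latency = latency, code_tags = NULL,
                 instance_tags = instance, raw = raw),
            class = "hed_event_record")
}

#' Read a tab-separated event table
#'
#' Numeric identifiers are interpreted as latencies (converted from samples
#' to seconds by dividing by `sampling_rate` when `latency_unit =
#' "samples"`); non-numeric identifiers are event codes.  Multiple tag
#' columns are concatenated with commas and parsed as one annotation per
#' event.
#'
#' @param x File path, TSV text, or character vector of lines.
#' @param id_column 1-based identifier column.
#' @param tag_columns 1-based tag column indices.
#' @param has_header Whether the first line is a header.
#' @param latency_unit `"seconds"` (default) or `"samples"`.
#' @param sampling_rate Sampling rate in Hz; required for `"samples"`.
#' @param code_column Optional 1-based column holding the event code when
#'   the identifier column holds latencies (files keyed by both codes and
#'   latencies).
#' @return An object of class `hed_event_table` with fields `records`,
#'   `header`, `id_column`, `tag_columns`.  A ragged row (missing a
#'   referenced column) raises a structural error naming the row.
#' @export
read_events_tsv <- function(x, id_column = 1L, tag_columns = 2L,
                            has_header = FALSE,
                            latency_unit = c("seconds", "samples"),
                            sampling_rate = NULL, code_column = NULL) {
  latency_unit <- match.arg(latency_unit)
  if (latency_unit == "samples" && is.null(sampling_rate)) {
    stop_hed("hed_usage_error",
             "sampling_rate is required when latency_unit = 'samples'")
  }
  lines <- read_lines_any(x)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  header <- NULL
  if (has_header && length(lines)) {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  need <- max(c(id_column, tag_columns, code_column))
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    raw <- split_fields(lines[i])
    if (length(raw) < need) {
      stop_hed("hed_parse_error",
               sprintf("row %d has %d column(s); %d required",
                       i + has_header, length(raw), need))
    }
    records[[i]] <- make_event_record(raw, id_column, tag_columns,
                                      latency_unit, sampling_rate, code_column)
  }
  structure(list(records = records, header = header,
                 id_column = id_column, tag_columns = tag_columns,
                 code_column = code_column),
            class = "hed_event_table")
}

#' The effective annotation of an event record
#'
#' The normalized union of the record's code-level tags (from a tag map) and
#' instance-level tags, with duplicates removed; ordering is normalization
#' ordering, so the result is deterministic.
#'
#' @param record A `hed_event_record`.
#' @param schema Optional schema for canonical capitalization.
#' @return A `hed_string`, or `NULL` for an untagged record.
#' @export
effective_tags <- function(record, schema = NULL) {
  parts <- c(
    if (!is.null(record$code_tags)) serialize_hed(record$code_tags),
    if (!is.null(record$instance_tags)) serialize_hed(record$instance_tags))
  if (!length(parts)) return(NULL)
  norm <- parse_hed(normalize_hed(parse_hed(paste(parts, collapse = ", ")),
                                  schema))
  # normalization sorts but keeps duplicates; drop repeated elements
  texts <- vapply(norm$elements, format, "")
  norm$elements <- norm$elements[!duplicated(texts)]
  parse_hed(serialize_hed(norm))
}

#' Write an event table as TSV
#'
#' The identifier column keeps its original text; the first tag column
#' receives the record's serialized annotation (the effective annotation
#' when code tags have been applied, otherwise the instance tags) and any
#' further tag columns are emptied, so re-reading yields the same
#' identifiers and tags.
#'
#' @param table A `hed_event_table`.
#' @param schema Optional schema used when merging code and instance tags.
#' @return TSV text.
#' @export
write_events_tsv <- function(table, schema = NULL) {
  lines <- character()
  if (!is.null(table$header)) lines <- paste(table$header, collapse = "\t")
  for (rec in table$records) {
    raw <- rec$raw
    tags <- if (!is.null(rec$code_tags)) effective_tags(rec, schema)
            else rec$instance_tags
    first <- TRUE
    for (col in table$tag_columns) {
      raw[col] <- if (first && !is.null(tags)) serialize_hed(tags) else ""
      first <- FALSE
    }
    lines <- c(lines, paste(raw, collapse = "\t"))
  }
  if (!length(lines)) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.hed_event_table <- function(x, ...) {
  n <- length(x$records)
  tagged <- sum(vapply(x$records, function(r)
    !is.null(r$instance_tags) || !is.null(r$code_tags), NA))
  cat(sprintf("HED event table: %d record(s), %d tagged\n", n, tagged))
  invisible(x)
}

#' Read / write a tag map (event code to HED string)
#'
#' A tag map is a two-column TSV (code, annotation) with an optional
#' `#version` comment line.  Codes are unique case-sensitively.
#'
#' @param x Map TSV text or file path.
#' @return [load_tagmap()] returns an object of class `hed_tagmap` (fields
#'   `entries`, a named list of `hed_string`s keyed by code, and `version`);
#'   [save_tagmap()] returns TSV text.
#' @export
load_tagmap <- function(x) {
  lines <- read_lines_any(x)
  version <- NA_character_
  vline <- grep("^#version\\b", lines)
  if (length(vline)) version <- trim(sub("^#version", "", lines[vline[1]]))
  lines <- lines[nzchar(trim(lines)) & !startsWith(lines, "#")]
  entries <- list()
  for (i in seq_along(lines)) {
    parts <- split_fields(lines[i])
    if (length(parts) < 2L) {
      stop_hed("hed_parse_error",
               sprintf("tag map line %d lacks a tag column", i))
    }
    code <- trim(parts[1])
    if (code %in% names(entries)) {
      stop_hed("hed_parse_error", sprintf("duplicate code '%s' in tag map", code))
    }
    entries[[code]] <- tryCatch(
      parse_hed(trim(parts[2])),
      error = function(e) stop_hed(
        "hed_parse_error",
        sprintf("tag map entry '%s': %s", code, conditionMessage(e))))
  }
  structure(list(entries = entries, version = version), class = "hed_tagmap")
}

#' @param map A `hed_tagmap`.
#' @rdname load_tagmap
#' @export
save_tagmap <- function(map) {
  lines <- character()
  if (!is.na(map$version)) lines <- paste("#version", map$version)
  for (code in names(map$entries)) {
    lines <- c(lines, paste(code, serialize_hed(map$entries[[code]]),
                            sep = "\t"))
  }
  if (!length(lines)) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Apply a tag map to an event table
#'
#' Records whose code appears in the map get their code-level tags set; the
#' effective annotation of a record becomes the normalized union of code and
#' instance tags (see [effective_tags()]).  Codes absent from the map are
#' left untagged and reported in the summary.
#'
#' @param table A `hed_event_table`.
#' @param map A `hed_tagmap`.
#' @return The tagged table, with a `"summary"` attribute: list with
#'   `records_tagged` and `codes_unmatched` (unique codes not in the map).
#'   Idempotent.
#' @export
apply_tagmap <- function(table, map) {
  tagged <- 0L
  unmatched <- character()
  for (i in seq_along(table$records)) {
    code <- table$records[[i]]$code
    if (is.na(code)) next
    hs <- map$entries[[code]]
    if (is.null(hs)) {
      unmatched <- c(unmatched, code)
    } else {
      table$records[[i]]$code_tags <- hs
      tagged <- tagged + 1L
    }
  }
  attr(table, "summary") <- list(records_tagged = tagged,
                                 codes_unmatched = sort(unique(unmatched)))
  table
}

#' Tag every event file in a collection with one call
#'
#' Applies a tag map to each file and writes the tagged table beside the
#' input with a `_tagged.tsv` suffix.
#'
#' @param paths Event file paths.
#' @param map A `hed_tagmap`.
#' @param id_column,tag_columns,has_header,code_column Passed to
#'   [read_events_tsv()].
#' @param schema Optional schema for the effective-tag merge.
#' @return Data frame with one row per file: `file`, `records`,
#'   `records_tagged`, `codes_unmatched`, `output`, `error` (message, or
#'   `NA`).  Unreadable files are recorded and processing continues.
#' @export
tag_directory <- function(paths, map, id_column = 1L, tag_columns = 2L,
                          has_header = FALSE, code_column = NULL,
                          schema = NULL) {
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      tab <- read_events_tsv(p, id_column, tag_columns, has_header,
                             code_column = code_column)
      tab <- apply_tagmap(tab, map)
      s <- attr(tab, "summary")
      out <- sub("\\.tsv$", "", p)
      out <- paste0(out, "_tagged.tsv")
      writeLines(sub("\n$", "", write_events_tsv(tab, schema)), out)
      data.frame(file = p, records = length(tab$records),
                 records_tagged = s$records_tagged,
                 codes_unmatched = length(s$codes_unmatched),
                 output = out, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(file = p, records = NA_integer_, records_tagged = NA_integer_,
                 codes_unmatched = NA_integer_, output = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  if (!length(rows)) {
    return(data.frame(file = character(), records = integer(),
                      records_tagged = integer(), codes_unmatched = integer(),
                      output = character(), error = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
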