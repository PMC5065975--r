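# MediaWiki text dialect: '''Name''' headings for top-level nodes, *-depth
# list lines for descendants, {attr, attr=value} markers, [description]
# brackets, an optional !Version line, and a !UnitClasses section of
# "* name {default=u}: u1, u2" lines.

parse_wiki_node_text <- function(text, lineno) {
  desc <- ""
  m <- regmatches(text, regexpr("\\[[^][]*\\]\\s*$", text))
  if (length(m) && nzchar(m)) {
    desc <- sub("^\\[", "", sub("\\]\\s*$", "", m))
    text <- sub("\\[[^][]*\\]\\s*$", "", text)
  }
  attrs <- list()
  m <- regmatches(text, regexpr("\\{[^{}]*\\}", text))
  if (length(m) && nzchar(m)) {
    body <- sub("^\\{", "", sub("\\}$", "", m))
    for (piece in trim(strsplit(body, ",", fixed = TRUE)[[1]])) {
      if (!nzchar(piece)) next
      if (grepl("=", piece, fixed = TRUE)) {
        kv <- strsplit(piece, "=", fixed = TRUE)[[1]]
        attrs[[trim(kv[1])]] <- trim(paste(kv[-1], collapse = "="))
      } else {
        attrs[[piece]] <- TRUE
      }
    }
    text <- sub("\\{[^{}]*\\}", "", text)
  }
  name <- trim(text)
  if (!nzchar(name)) {
    stop_hed("hed_parse_error",
             sprintf("wiki line %d: empty node name", lineno))
  }
  list(name = name, description = desc, attrs = attrs)
}

#' Parse a schema from its MediaWiki text form
#'
#' @param x Wiki text, a file path, or a character vector of lines.
#' @return A `hed_schema` equal to the one the XML form of the same
#'   vocabulary yields.  An indentation jump of more than one level raises a
#'   structure error naming the line.
#' @export
parse_schema_wiki <- function(x) {
  lines <- read_lines_any(x)
  version <- "2.0"
  roots <- list()
  ucs <- list()
  # stack[[d]] holds the partially built node at depth d (children collected
  # in reverse order then finalized on pop).
  stack <- list()
  in_units <- FALSE

  finalize <- function(frame) {
    hed_node(frame$name, frame$children, description = frame$description,
             attrs = frame$attrs)
  }
  pop_to <- function(depth) {
    while (length(stack) > depth) {
      d <- length(stack)
      node <- finalize(stack[[d]])
      stack[[d]] <<- NULL
      if (d == 1L) {
        roots[[length(roots) + 1L]] <<- node
      } else {
        stack[[d - 1L]]$children <<-
          c(stack[[d - 1L]]$children, list(node))
      }
    }
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trim(line))) next
    if (grepl("^!Version\\b", line)) {
      version <- trim(sub("^!Version", "", line))
      next
    }
    if (grepl("^!UnitClasses\\s*$", line)) {
      pop_to(0L)
      in_units <- TRUE
      next
    }
    if (in_units) {
      body <- sub("^\\*\\s*", "", line)
      if (!grepl(":", body, fixed = TRUE)) {
        stop_hed("hed_parse_error",
                 sprintf("wiki line %d: malformed unit class line", i))
      }
      head <- trim(sub(":[^:]*$", "", body))
      units <- trim(strsplit(sub("^.*:", "", body), ",", fixed = TRUE)[[1]])
      info <- parse_wiki_node_text(head, i)
      def <- info$attrs$default %||% units[1]
      ucs[[info$name]] <- hed_unit_class(info$name, units, def)
      next
    }
    if (grepl("^'''", line)) {
      m <- regmatches(line, regexpr("^'''[^']+'''", line))
      if (!length(m)) {
        stop_hed("hed_parse_error",
                 sprintf("wiki line %d: malformed heading", i))
      }
      name <- sub("^'''", "", sub("'''$", "", m))
      rest <- trim(sub("^'''[^']+'''", "", line))
      info <- parse_wiki_node_text(paste(name, rest), i)
      pop_to(0L)
      stack[[1]] <- c(info, list(children = list()))
      next
    }
    if (grepl("^\\*", line)) {
      stars <- nchar(regmatches(line, regexpr("^\\*+", line)))
      depth <- stars + 1L
      if (depth > length(stack) + 1L) {
        stop_hed("hed_parse_error",
                 sprintf("wiki line %d: indentation jumps more than one level", i))
      }
      if (depth == 1L || length(stack) == 0L) {
        stop_hed("hed_parse_error",
                 sprintf("wiki line %d: list item outside a heading", i))
      }
      info <- parse_wiki_node_text(sub("^\\*+\\s*", "", line), i)
      pop_to(depth - 1L)
      stack[[depth]] <- c(info, list(children = list()))
      next
    }
    stop_hed("hed_parse_error",
             sprintf("wiki line %d: unrecognized line '%s'", i, trim(line)))
  }
  pop_to(0L)
  hed_schema(roots, ucs, version = version)
}

#' Serialize a schema to its MediaWiki text form
#'
#' @param schema A `hed_schema`.
#' @return Wiki text (single string) that [parse_schema_wiki()] reads back
#'   to an equal schema.
#' @export
serialize_schema_wiki <- function(schema) {
  attr_text <- function(attrs) {
    if (!length(attrs)) return("")
    parts <- vapply(names(attrs), function(nm) {
      v <- attrs[[nm]]
      if (isTRUE(v)) nm else paste0(nm, "=", as.character(v))
    }, "")
    paste0(" {", paste(parts, collapse = ", "), "}")
  }
  desc_text <- function(d) if (nzchar(d)) paste0(" [", d, "]") else ""
  lines <- c(paste("!Version", schema$version))
  emit <- function(node, depth) {
    marker <- if (depth == 1L) sprintf("'''%s'''", node$name)
              else paste0(strrep("*", depth - 1L), " ", node$name)
    lines <<- c(lines, paste0(marker, attr_text(node$attrs),
                              desc_text(node$description)))
    for (ch in node$children) emit(ch, depth + 1L)
  }
  for (r in schema$roots) emit(r, 1L)
  if (length(schema$unit_classes)) {
    lines <- c(lines, "!UnitClasses")
    for (uc in schema$unit_classes) {
      lines <- c(lines, sprintf("* %s {default=%s}: %s", uc$name, uc$default,
                                paste(uc$units, collapse = ", ")))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
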