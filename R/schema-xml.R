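# XML dialect: one element per node, <name> and <description> child
# elements, nested <node> elements, attribute flags as lowerCamelCase XML
# attributes, unit classes in a trailing <unitClasses> section.

#' Parse a schema from its XML form
#'
#' @param x XML text, a file path, or an `xml2` document.
#' @return A `hed_schema`.  Malformed XML raises a parse error (with the
#'   line number reported by the XML parser); duplicate sibling names and
#'   unit-class violations raise schema errors.
#' @export
parse_schema_xml <- function(x) {
  doc <- tryCatch({
    if (inherits(x, "xml_document")) x
    else if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x))
      xml2::read_xml(x)
    else xml2::read_xml(paste(x, collapse = "\n"))
  }, error = function(e) {
    stop_hed("hed_parse_error", paste("XML parse error:", conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  version <- xml2::xml_attr(root, "version")
  if (is.na(version)) version <- "2.0"

  parse_node <- function(el) {
    kids <- xml2::xml_children(el)
    kid_names <- xml2::xml_name(kids)
    name <- xml2::xml_text(kids[kid_names == "name"][1])
    desc_el <- kids[kid_names == "description"]
    desc <- if (length(desc_el)) xml2::xml_text(desc_el[1]) else ""
    attrs <- as.list(xml2::xml_attrs(el))
    children <- lapply(kids[kid_names == "node"], parse_node)
    hed_node(name, children, description = desc, attrs = attrs)
  }

  top <- xml2::xml_children(root)
  roots <- lapply(top[xml2::xml_name(top) == "node"], parse_node)

  ucs <- list()
  uc_section <- top[xml2::xml_name(top) == "unitClasses"]
  if (length(uc_section)) {
    for (el in xml2::xml_children(uc_section[[1]])) {
      kids <- xml2::xml_children(el)
      kid_names <- xml2::xml_name(kids)
      nm <- xml2::xml_text(kids[kid_names == "name"][1])
      def <- xml2::xml_text(kids[kid_names == "defaultUnit"][1])
      units <- xml2::xml_text(
        xml2::xml_find_all(el, "./units/unit"))
      if (!def %in% units) {
        stop_hed("hed_schema_error",
                 sprintf("unit class '%s': default unit '%s' not in allowed units",
                         nm, def))
      }
      ucs[[nm]] <- hed_unit_class(nm, units, def)
    }
  }
  hed_schema(roots, ucs, version = version)
}

#' Serialize a schema to its XML form
#'
#' `parse_schema_xml(serialize_schema_xml(s))` reproduces `s` exactly
#' (names, descriptions, attributes, unit classes, order).
#'
#' @param schema A `hed_schema`.
#' @return XML text (single string).
#' @export
serialize_schema_xml <- function(schema) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    x
  }
  esc_attr <- function(x) gsub("\"", "&quot;", esc(x), fixed = TRUE)
  attr_text <- function(attrs) {
    if (!length(attrs)) return("")
    vals <- vapply(names(attrs), function(nm) {
      v <- attrs[[nm]]
      v <- if (isTRUE(v)) "true" else as.character(v)
      sprintf(' %s="%s"', nm, esc_attr(v))
    }, "")
    paste(vals, collapse = "")
  }
  lines <- character()
  emit <- function(node, indent) {
    pad <- strrep("  ", indent)
    lines <<- c(lines, sprintf("%s<node%s>", pad, attr_text(node$attrs)),
                sprintf("%s  <name>%s</name>", pad, esc(node$name)))
    if (nzchar(node$description)) {
      lines <<- c(lines, sprintf("%s  <description>%s</description>",
                                 pad, esc(node$description)))
    }
    for (ch in node$children) emit(ch, indent + 1L)
    lines <<- c(lines, sprintf("%s</node>", pad))
  }
  lines <- c(sprintf('<HED version="%s">', esc_attr(schema$version)))
  for (r in schema$roots) emit(r, 1L)
  if (length(schema$unit_classes)) {
    lines <- c(lines, "  <unitClasses>")
    for (uc in schema$unit_classes) {
      lines <- c(lines,
                 "    <unitClass>",
                 sprintf("      <name>%s</name>", esc(uc$name)),
                 sprintf("      <defaultUnit>%s</defaultUnit>", esc(uc$default)),
                 "      <units>",
                 sprintf("        <unit>%s</unit>", esc(uc$units)),
                 "      </units>",
                 "    </unitClass>")
    }
    lines <- c(lines, "  </unitClasses>")
  }
  lines <- c(lines, "</HED>")
  paste0(paste(lines, collapse = "\n"), "\n")
}
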