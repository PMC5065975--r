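# Schema model: hierarchical vocabulary, node attributes, unit classes,
# path resolution.

# Node attribute flags with defined semantics; everything else supplied in a
# schema file is carried opaquely and round-tripped.
.flag_attrs <- c("required", "childRequired", "unique", "recommended",
                 "takesValue", "isNumeric", "extensionAllowed")
.known_attrs <- c(.flag_attrs, "position", "type", "unitClass",
                  "predicateType", "default")

#' Create a schema node
#'
#' A node has a name (one path segment), an optional description, a set of
#' attributes and an ordered list of child nodes.  A value-taking node is
#' named `"#"`, carries `takesValue` and has no children.
#'
#' @param name Path segment; must not contain `/`, `,`, `(`, `)` or `~`.
#' @param ... Child nodes (`hed_node` objects).
#' @param description Free-text description.
#' @param attrs Named list of node attributes.  Recognised flags:
#'   `required`, `childRequired`, `unique`, `recommended`, `takesValue`,
#'   `isNumeric`, `extensionAllowed`; recognised valued attributes:
#'   `position` (integer), `type`, `unitClass`, `predicateType`
#'   (`"subclass"` or `"property"`; the default when absent is subclass),
#'   `default`.  Unknown attributes are preserved as character.
#' @return An object of class `hed_node`.
#' @export
hed_node <- function(name, ..., description = "", attrs = list()) {
  if (grepl("[/,()~]", name)) {
    stop_hed("hed_schema_error",
             sprintf("node name '%s' contains a reserved character", name))
  }
  kids <- list(...)
  if (length(kids) == 1L && is.list(kids[[1]]) &&
      !inherits(kids[[1]], "hed_node")) {
    kids <- kids[[1]]
  }
  attrs <- normalize_attrs(attrs)
  if (name == "#" && length(kids) > 0L) {
    stop_hed("hed_schema_error", "a '#' (value) node cannot have children")
  }
  structure(list(name = name, description = description,
                 attrs = attrs, children = kids),
            class = "hed_node")
}

# Canonical attribute storage: flags kept only when TRUE (as logical),
# position as integer, known valued attributes and unknowns as character,
# names sorted for deterministic equality.
normalize_attrs <- function(attrs) {
  if (length(attrs) == 0L) return(structure(list(), names = character()))
  out <- list()
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (nm %in% .flag_attrs) {
      v <- isTRUE(v) || identical(v, "true") || identical(v, "TRUE")
      if (v) out[[nm]] <- TRUE
    } else if (nm == "position") {
      out[[nm]] <- as.integer(v)
    } else {
      out[[nm]] <- as.character(v)
    }
  }
  out[order(names(out))]
}

#' Create a unit class
#'
#' @param name Unit-class name (unique within a schema registry).
#' @param units Character vector of allowed unit tokens.
#' @param default Default unit, applied to bare numeric values; must be one
#'   of `units`.
#' @return An object of class `hed_unit_class`.
#' @export
hed_unit_class <- function(name, units, default) {
  units <- as.character(units)
  if (length(units) == 0L) {
    stop_hed("hed_schema_error",
             sprintf("unit class '%s' has no allowed units", name))
  }
  if (!default %in% units) {
    stop_hed("hed_schema_error",
             sprintf("unit class '%s': default unit '%s' is not among allowed units",
                     name, default))
  }
  structure(list(name = name, units = units, default = default),
            class = "hed_unit_class")
}

#' The unit classes shipped with the package
#'
#' Time, physical length, angle, frequency, area, volume, currency, velocity
#' and jerk, with SI units and defaults.
#'
#' @return Named list of [hed_unit_class()] objects.
#' @export
default_unit_classes <- function() {
  ucs <- list(
    hed_unit_class("time", c("s", "ms"), "s"),
    hed_unit_class("physicalLength", c("m", "cm", "mm"), "m"),
    hed_unit_class("angle", c("degree", "radian"), "radian"),
    hed_unit_class("frequency", "Hz", "Hz"),
    hed_unit_class("area", "m^2", "m^2"),
    hed_unit_class("volume", "m^3", "m^3"),
    hed_unit_class("currency", "$", "$"),
    hed_unit_class("velocity", "m-per-s", "m-per-s"),
    hed_unit_class("jerk", "m-per-s^3", "m-per-s^3")
  )
  stats::setNames(ucs, vapply(ucs, `[[`, "", "name"))
}

#' Assemble a schema from root nodes
#'
#' Builds the case-insensitive path index and validates basic structure
#' (duplicate sibling names and unit-class references raise errors; use
#' [check_schema()] for a non-raising report).
#'
#' @param roots List of root [hed_node()] objects.
#' @param unit_classes Named list of [hed_unit_class()] objects.
#' @param version Version text carried in serialized forms.
#' @param check When `TRUE` (default), structural violations raise; pass
#'   `FALSE` to build a deliberately faulty schema for inspection with
#'   [check_schema()].
#' @return An object of class `hed_schema`.
#' @export
hed_schema <- function(roots = list(), unit_classes = list(), version = "2.0",
                       check = TRUE) {
  if (inherits(roots, "hed_node")) roots <- list(roots)
  if (length(unit_classes)) {
    names(unit_classes) <- vapply(unit_classes, `[[`, "", "name")
    unit_classes <- unit_classes[order(names(unit_classes))]
  }
  s <- structure(list(version = version, roots = roots,
                      unit_classes = unit_classes, index = NULL),
                 class = "hed_schema")
  s$index <- build_schema_index(s)
  if (check) {
    issues <- check_schema(s)
    fatal <- issues[issues$code %in% c("DUPLICATE_SIBLING", "UNIT_CLASS_MISSING",
                                       "DEFAULT_UNIT_INVALID"), , drop = FALSE]
    if (nrow(fatal)) {
      stop_hed("hed_schema_error",
               paste(fatal$message, collapse = "; "))
    }
  }
  s
}

# Flat index: one entry per node keyed by lower-cased '/'-led path.
# Entries record the canonical path, depth, attributes, leaf status and the
# attributes of a '#' child when one exists.
build_schema_index <- function(schema) {
  index <- list()
  walk <- function(node, prefix) {
    path <- paste0(prefix, "/", node$name)
    kid_names <- vapply(node$children, `[[`, "", "name")
    hash <- which(kid_names == "#")
    index[[tolower(path)]] <<- list(
      path = path,
      name = node$name,
      depth = length(split_tag_path(path)),
      attrs = node$attrs,
      is_leaf = length(node$children) == 0L,
      has_hash_child = length(hash) > 0L,
      hash_attrs = if (length(hash)) node$children[[hash[1]]]$attrs else NULL
    )
    for (ch in node$children) walk(ch, path)
  }
  for (r in schema$roots) walk(r, "")
  index
}

#' Resolve a tag path against a schema
#'
#' Matching is case-insensitive.  The result kind is one of:
#' \describe{
#'   \item{exact}{the full path names a schema node;}
#'   \item{valueMatch}{all but the final segment names a node with a `#`
#'     (value-taking) child; the final segment is the supplied value;}
#'   \item{extension}{a strict prefix matches and the matched node is a leaf
#'     or carries `extensionAllowed` (leaves are always extensible);}
#'   \item{miss}{anything else; the deepest valid ancestor is reported.}
#' }
#'
#' @param schema A `hed_schema`.
#' @param path Tag path text, segments separated by `/`.
#' @return An object of class `hed_path_match` with fields `kind`, `path`
#'   (canonical matched path or `NA`), `attrs`, `matched_depth`,
#'   `extension_segments`, `value` and `hash_attrs`.
#' @export
hed_locate <- function(schema, path) {
  segs <- if (inherits(path, "hed_tag")) path$segments else split_tag_path(path)
  if (length(segs) == 0L) {
    stop_hed("hed_usage_error", "empty tag path")
  }
  n <- length(segs)
  lower <- tolower(segs)
  hit <- NULL
  k <- 0L
  for (j in seq(n, 1L)) {
    key <- paste0("/", paste(lower[seq_len(j)], collapse = "/"))
    e <- schema$index[[key]]
    if (!is.null(e)) { hit <- e; k <- j; break }
  }
  res <- list(kind = "miss", path = if (is.null(hit)) NA_character_ else hit$path,
              attrs = if (is.null(hit)) list() else hit$attrs,
              matched_depth = k,
              extension_segments = if (k < n) segs[(k + 1L):n] else character(),
              value = NA_character_,
              hash_attrs = if (is.null(hit)) NULL else hit$hash_attrs)
  if (k == n) {
    res$kind <- "exact"
  } else if (!is.null(hit) && k == n - 1L && hit$has_hash_child) {
    res$kind <- "valueMatch"
    res$value <- segs[n]
    res$extension_segments <- character()
  } else if (!is.null(hit) &&
             (hit$is_leaf || isTRUE(hit$attrs$extensionAllowed))) {
    res$kind <- "extension"
  }
  structure(res, class = "hed_path_match")
}

#' Search node names for a text fragment
#'
#' Returns the full paths of all nodes (excluding `#` value nodes) whose
#' final segment contains `fragment`, case-insensitively, ordered by path.
#'
#' @param schema A `hed_schema`.
#' @param fragment Non-empty search text.
#' @return Character vector of canonical paths.
#' @export
schema_search <- function(schema, fragment) {
  if (!nzchar(fragment)) stop_hed("hed_usage_error", "empty search fragment")
  names_lower <- vapply(schema$index, function(e) tolower(e$name), "")
  paths <- vapply(schema$index, `[[`, "", "path")
  hits <- paths[names_lower != "#" &
                  grepl(tolower(fragment), names_lower, fixed = TRUE)]
  unname(hits[ci_order(hits)])
}

#' Paths at a given depth
#'
#' Depth 1 is the root level.  Together with deeper levels this partitions
#' the schema: summing counts over all levels gives the total node count.
#'
#' @param schema A `hed_schema`.
#' @param level Positive integer depth.
#' @return Character vector of canonical paths at exactly that depth.
#' @export
nodes_at_level <- function(schema, level) {
  if (!is.numeric(level) || level < 1) {
    stop_hed("hed_usage_error", "level must be a positive integer")
  }
  depths <- vapply(schema$index, `[[`, 0L, "depth")
  paths <- vapply(schema$index, `[[`, "", "path")
  hits <- paths[depths == as.integer(level)]
  unname(hits[ci_order(hits)])
}

#' Self-check a schema
#'
#' Reports duplicate sibling names (case-insensitive), references to missing
#' unit classes, default units outside the allowed set, `#` nodes with
#' children or without `takesValue`, and `isNumeric`/`unitClass` on nodes
#' that do not take values.
#'
#' @param schema A `hed_schema`.
#' @return A data frame of issues (`code`, `message`, `path`); zero rows for
#'   a clean schema.
#' @export
check_schema <- function(schema) {
  issues <- list()
  add <- function(code, message, path = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, message = message, path = path,
      stringsAsFactors = FALSE)
  }
  walk <- function(node, prefix) {
    path <- paste0(prefix, "/", node$name)
    kid_names <- vapply(node$children, `[[`, "", "name")
    dup <- duplicated(tolower(kid_names))
    for (nm in unique(kid_names[dup])) {
      add("DUPLICATE_SIBLING",
          sprintf("duplicate sibling name '%s' under %s", nm, path), path)
    }
    a <- node$attrs
    if (node$name == "#") {
      if (length(node$children)) {
        add("HASH_WITH_CHILDREN",
            sprintf("value node %s has children", path), path)
      }
      if (!isTRUE(a$takesValue)) {
        add("HASH_NOT_VALUE",
            sprintf("'#' node %s lacks takesValue", path), path)
      }
    }
    if (isTRUE(a$isNumeric) && !isTRUE(a$takesValue)) {
      add("NUMERIC_NOT_VALUE",
          sprintf("%s is marked isNumeric but not takesValue", path), path)
    }
    if (!is.null(a$unitClass)) {
      if (!isTRUE(a$takesValue)) {
        add("UNITCLASS_NOT_VALUE",
            sprintf("%s has a unit class but not takesValue", path), path)
      }
      if (!a$unitClass %in% names(schema$unit_classes)) {
        add("UNIT_CLASS_MISSING",
            sprintf("%s references missing unit class '%s'", path, a$unitClass),
            path)
      }
    }
    for (ch in node$children) walk(ch, path)
  }
  root_names <- vapply(schema$roots, `[[`, "", "name")
  for (nm in unique(root_names[duplicated(tolower(root_names))])) {
    add("DUPLICATE_SIBLING", sprintf("duplicate root name '%s'", nm))
  }
  for (r in schema$roots) walk(r, "")
  for (uc in schema$unit_classes) {
    if (!uc$default %in% uc$units) {
      add("DEFAULT_UNIT_INVALID",
          sprintf("unit class '%s': default '%s' not in allowed units",
                  uc$name, uc$default))
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), message = character(), path = character(),
               stringsAsFactors = FALSE)
}

# Canonical comparable form: strips the derived index.
schema_canonical <- function(schema) {
  strip <- function(node) {
    list(name = node$name, description = node$description,
         attrs = node$attrs, children = lapply(node$children, strip))
  }
  list(version = schema$version,
       roots = lapply(schema$roots, strip),
       unit_classes = lapply(schema$unit_classes, unclass))
}

#' Test two schemas for structural equality
#'
#' Compares names, descriptions, attributes, child order, unit classes and
#' version; the derived index is ignored.
#'
#' @param a,b `hed_schema` objects.
#' @return Logical.
#' @export
schema_equal <- function(a, b) {
  identical(schema_canonical(a), schema_canonical(b))
}

#' @export
print.hed_schema <- function(x, ...) {
  cat(sprintf("HED schema (version %s): %d root(s), %d node(s), %d unit class(es)\n",
              x$version, length(x$roots), length(x$index),
              length(x$unit_classes)))
  for (r in x$roots) cat("  /", r$name, "\n", sep = "")
  invisible(x)
}

#' @export
print.hed_path_match <- function(x, ...) {
  cat(sprintf("<%s> %s", x$kind,
              if (is.na(x$path)) "(no ancestor)" else x$path))
  if (!is.na(x$value)) cat(sprintf(" value=%s", x$value))
  if (length(x$extension_segments)) {
    cat(" +", join_tag_path(x$extension_segments))
  }
  cat("\n")
  invisible(x)
}
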