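# Seeded generators: random schemas for round-trip testing and event tables
# with a precise ledger of every injected fault and planted query match.
# Both are pure functions of their arguments including the seed.

#' Generate a random schema
#'
#' Builds a deterministic random vocabulary of bounded depth with
#' randomized `extensionAllowed` flags and value-taking (`#`) leaves, some
#' of which draw a unit class from the default registry.  The result always
#' passes [check_schema()].
#'
#' @param seed Integer seed.
#' @param depth Maximum depth (1-7).
#' @param branching Mean number of children per interior node.
#' @return A `hed_schema`.
#' @export
gen_schema <- function(seed, depth = 4L, branching = 3L) {
  if (depth < 1L || depth > 7L) {
    stop_hed("hed_usage_error", "depth must be between 1 and 7")
  }
  ucs <- default_unit_classes()
  with_seed(seed, {
    counter <- 0L
    gen_node <- function(level) {
      counter <<- counter + 1L
      name <- paste0("Node", counter,
                     paste(sample(letters, 2L, replace = TRUE), collapse = ""))
      attrs <- list()
      kids <- list()
      n_kids <- if (level >= depth) 0L else max(0L, stats::rpois(1L, branching - 1L))
      if (n_kids == 0L && level < depth && stats::runif(1) < 0.3) {
        # value-taking leaf
        ha <- list(takesValue = TRUE)
        if (stats::runif(1) < 0.5) ha$isNumeric <- TRUE
        if (stats::runif(1) < 0.4) {
          ha$unitClass <- sample(names(ucs), 1L)
          ha$isNumeric <- TRUE
        }
        kids <- list(hed_node("#", attrs = ha))
      } else if (n_kids > 0L) {
        kids <- lapply(seq_len(n_kids), function(i) gen_node(level + 1L))
      }
      if (stats::runif(1) < 0.25) attrs$extensionAllowed <- TRUE
      if (stats::runif(1) < 0.15 && length(kids)) attrs$childRequired <- TRUE
      desc <- if (stats::runif(1) < 0.5)
        paste("Generated node", counter) else ""
      hed_node(name, kids, description = desc, attrs = attrs)
    }
    n_roots <- sample(2:4, 1L)
    roots <- lapply(seq_len(n_roots), function(i) gen_node(1L))
    hed_schema(roots, ucs, version = sprintf("gen-%d", seed))
  })
}

#' Generate an annotated event table with an error-injection ledger
#'
#' Events have monotone latencies (column 1), an event code (column 2) and
#' a valid annotation (column 3).  A fraction `error_rate` of the rows is
#' corrupted by one of five faults - a misspelled path segment
#' (`UNKNOWN_TAG`), a non-numeric value on a numeric wildcard
#' (`NOT_NUMERIC`), a wrong unit (`UNIT_INVALID`), a dropped
#' `/Event/Category` tag (`REQUIRED_MISSING`) or an overlong label
#' (`LABEL_TOO_LONG`) - and every corruption is recorded in the ledger, so
#' a validator run over the output must reproduce the ledger exactly.
#'
#' @param seed Integer seed.
#' @param n_events Number of events.
#' @param error_rate Fraction of rows corrupted (0-1).
#' @param schema Schema the clean rows validate against (default the
#'   fixture schema).
#' @param map Optional `hed_tagmap`; when given, event codes are drawn from
#'   its entries instead of the built-in code pool.
#' @return List with `text` (the TSV), `ledger` (data frame `row`,
#'   `column`, `code`, `tag`), `planted` (named integer vector of expected
#'   [select_events()] counts per query prefix), and `seed`.
#' @export
gen_events <- function(seed, n_events = 100L, error_rate = 0,
                       schema = fixture_schema(), map = NULL) {
  if (error_rate < 0 || error_rate > 1) {
    stop_hed("hed_usage_error", "error_rate must be within [0, 1]")
  }
  categories <- c("Experimental stimulus", "Participant response",
                  "Environmental", "Incidental")
  extras <- c("/Item/Object/Furniture/Chair",
              "/Item/2D shape/Ellipse/Circle",
              "/Attribute/Visual/Color/Red",
              "/Attribute/Duration/0.5 s",
              "/Sensory presentation/Visual")
  planted_prefix <- "/Participant/Effect/Cognitive/Target"
  codes <- if (!is.null(map)) names(map$entries) else
    c("square", "rt", "stim1", "stim2")
  tagcol <- 3L

  with_seed(seed, {
    latency <- round(cumsum(stats::runif(n_events, 0.5, 2)), 3)
    rows <- character(n_events)
    ledger <- list()
    planted <- 0L
    n_bad <- round(error_rate * n_events)
    bad_rows <- if (n_bad) sort(sample(n_events, n_bad)) else integer()
    faults <- c("UNKNOWN_TAG", "NOT_NUMERIC", "UNIT_INVALID",
                "REQUIRED_MISSING", "LABEL_TOO_LONG")
    fault_of <- if (n_bad) sample(faults, n_bad, replace = TRUE) else character()

    for (i in seq_len(n_events)) {
      code <- sample(codes, 1L)
      cat_tag <- sprintf("/Event/Category/%s", sample(categories, 1L))
      label_value <- sprintf("Evt%d", sample(99L, 1L))
      label_tag <- sprintf("/Event/Label/%s", label_value)
      desc_tag <- sprintf("/Event/Description/Generated event number %d", i)
      tags <- c(cat_tag, label_tag, desc_tag)
      plant_here <- stats::runif(1) < 0.3
      if (plant_here) tags <- c(tags, planted_prefix)
      tags <- c(tags, sample(extras, sample(0:2, 1L)))

      fault <- fault_of[match(i, bad_rows)]
      if (!is.na(fault)) {
        bad_tag <- switch(fault,
          UNKNOWN_TAG = sprintf("/Itemm/Bogus%d", i),
          NOT_NUMERIC = "/Attribute/Presentation fraction/abc",
          UNIT_INVALID = "/Attribute/Duration/5 parsecs",
          LABEL_TOO_LONG = NA_character_,
          REQUIRED_MISSING = NA_character_)
        if (fault == "UNKNOWN_TAG" || fault == "NOT_NUMERIC" ||
            fault == "UNIT_INVALID") {
          tags <- c(tags, bad_tag)
          ledger[[length(ledger) + 1L]] <- data.frame(
            row = i, column = tagcol, code = fault, tag = bad_tag,
            stringsAsFactors = FALSE)
        } else if (fault == "REQUIRED_MISSING") {
          tags <- setdiff(tags, cat_tag)
          ledger[[length(ledger) + 1L]] <- data.frame(
            row = i, column = NA_integer_, code = fault,
            tag = "/Event/Category", stringsAsFactors = FALSE)
        } else { # LABEL_TOO_LONG
          long_value <- paste0("ThisLabelIsFarTooLongRow", i)
          long_tag <- sprintf("/Event/Label/%s", long_value)
          tags[tags == label_tag] <- long_tag
          ledger[[length(ledger) + 1L]] <- data.frame(
            row = i, column = tagcol, code = fault, tag = long_tag,
            stringsAsFactors = FALSE)
        }
      }
      if (plant_here) planted <- planted + 1L
      rows[i] <- paste(format(latency[i], trim = TRUE), code,
                       paste(tags, collapse = ", "), sep = "\t")
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(row = integer(), column = integer(), code = character(),
                 tag = character(), stringsAsFactors = FALSE)
    list(text = paste0(paste(rows, collapse = "\n"), "\n"),
         ledger = ledger,
         planted = stats::setNames(planted, planted_prefix),
         seed = seed)
  })
}
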