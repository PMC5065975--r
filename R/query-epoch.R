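# Tag-prefix queries over tagged event tables, epoch extraction anchored at
# event latencies, and tag-usage summaries.

#' Build a tag query
#'
#' @param prefixes Non-empty character vector of tag-path prefixes.
#' @param mode `"any"` (some prefix matches some tag) or `"all"` (every
#'   prefix matches some tag).
#' @return An object of class `hed_query`.
#' @export
hed_query <- function(prefixes, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!length(prefixes) || any(!nzchar(trim(prefixes)))) {
    stop_hed("hed_usage_error", "query needs at least one non-empty prefix")
  }
  structure(list(prefixes = vapply(prefixes, function(p)
    join_tag_path(split_tag_path(p)), "", USE.NAMES = FALSE), mode = mode),
    class = "hed_query")
}

#' Does a tag start with a path prefix?
#'
#' True iff the prefix's segments equal the tag's leading segments,
#' case-insensitively and whole segments only, so `/Item/Object` matches
#' `/Item/Object/Vehicle/Car` but not `/Item/Objective/X`.
#'
#' @param tag A `hed_tag` or tag text.
#' @param prefix Tag-path prefix text.
#' @return Logical.
#' @export
tag_matches <- function(tag, prefix) {
  tsegs <- if (inherits(tag, "hed_tag")) tag$segments else split_tag_path(tag)
  psegs <- split_tag_path(prefix)
  if (!length(psegs) || !length(tsegs)) {
    stop_hed("hed_usage_error", "tag and prefix must be non-empty")
  }
  length(psegs) <= length(tsegs) &&
    identical(tolower(psegs), tolower(tsegs[seq_along(psegs)]))
}

#' Does an annotation string satisfy a query?
#'
#' All tags are considered: top level and inside all groups and clauses.
#'
#' @param hs A `hed_string` or annotation text.
#' @param query A `hed_query` (or character vector of prefixes, mode "any").
#' @return Logical.
#' @export
string_matches <- function(hs, query) {
  if (is.character(hs)) hs <- parse_hed(hs)
  if (is.character(query)) query <- hed_query(query)
  tags <- flatten_hed_tags(hs)
  if (!length(tags)) return(FALSE)
  hit <- vapply(query$prefixes, function(p) {
    any(vapply(tags, tag_matches, NA, prefix = p))
  }, NA)
  if (query$mode == "all") all(hit) else any(hit)
}

#' Select events matching a tag query
#'
#' Order-preserving filter on the effective annotation of each record (code
#' tags merged with instance tags).
#'
#' @param table A `hed_event_table`.
#' @param query A `hed_query` or character vector of prefixes.
#' @param schema Optional schema for the effective-tag merge.
#' @return A `hed_event_table` of the matching records, with an
#'   `"indices"` attribute giving their 1-based positions in the input.
#' @export
select_events <- function(table, query, schema = NULL) {
  if (is.character(query)) query <- hed_query(query)
  keep <- vapply(seq_along(table$records), function(i) {
    hs <- effective_tags(table$records[[i]], schema)
    !is.null(hs) && string_matches(hs, query)
  }, NA)
  out <- table
  out$records <- table$records[keep]
  attr(out, "indices") <- which(keep)
  out
}

#' Extract epoch windows time-locked to matching events
#'
#' One epoch per selected event, anchored at its latency: the window is
#' `[latency - pre, latency + post]` seconds.  Windows are abstract time
#' intervals; the start may be negative and clipping to recording bounds is
#' the caller's concern.
#'
#' @param table A `hed_event_table` (records selected must have latencies).
#' @param query A `hed_query` or character vector of prefixes.
#' @param pre Seconds before the anchor (>= 0).
#' @param post Seconds after the anchor (>= 0).
#' @param schema Optional schema for the effective-tag merge.
#' @return Data frame with columns `event_index`, `start`, `end`, `anchor`.
#' @export
extract_epochs <- function(table, query, pre = 0, post = 0, schema = NULL) {
  if (pre < 0 || post < 0) {
    stop_hed("hed_usage_error", "pre and post must be non-negative")
  }
  sel <- select_events(table, query, schema)
  idx <- attr(sel, "indices")
  anchors <- vapply(sel$records, `[[`, 0, "latency")
  bad <- which(is.na(anchors))
  if (length(bad)) {
    rec <- sel$records[[bad[1]]]
    stop_hed("hed_usage_error",
             sprintf("selected event %d (code '%s') has no latency",
                     idx[bad[1]], rec$code))
  }
  data.frame(event_index = idx, start = anchors - pre, end = anchors + post,
             anchor = anchors)
}

#' Summarize tag usage at a hierarchy level
#'
#' For each schema path truncated to `level` segments, counts the event
#' instances having at least one tag under that path; an instance counts
#' once per truncated path even when several of its tags fall under it.
#'
#' @param tables A `hed_event_table` or list of them.
#' @param level Positive integer truncation depth (1 = top-level classes).
#' @param schema Optional schema for canonical path capitalization (unknown
#'   paths are folded to lower case).
#' @return Named integer vector, truncated path -> instance count, ordered
#'   by path.
#' @export
summarize_tags <- function(tables, level, schema = NULL) {
  if (inherits(tables, "hed_event_table")) tables <- list(tables)
  if (!is.numeric(level) || level < 1) {
    stop_hed("hed_usage_error", "level must be a positive integer")
  }
  counts <- integer()
  for (tab in tables) {
    for (rec in tab$records) {
      hs <- effective_tags(rec, schema)
      if (is.null(hs)) next
      paths <- character()
      for (tag in flatten_hed_tags(hs)) {
        if (length(tag$segments) < level) next
        trunc <- tag$segments[seq_len(level)]
        key <- if (is.null(schema)) tolower(join_tag_path(trunc))
               else canonical_tag_text(make_hed_tag(join_tag_path(trunc)), schema)
        paths <- c(paths, key)
      }
      for (p in unique(paths)) {
        counts[p] <- (if (p %in% names(counts)) counts[[p]] else 0L) + 1L
      }
    }
  }
  counts[ci_order(names(counts))]
}
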