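# Shared fixtures and independent oracles.

fx <- fixture_schema()
fx_examples <- example_annotations()

# --- independent path-resolution oracle -------------------------------------
# Walks the schema tree directly (never the index) and classifies the match
# with its own logic.
oracle_locate <- function(schema, path) {
  segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  n <- length(segs)
  node <- NULL
  kids <- schema$roots
  depth <- 0L
  for (seg in segs) {
    nms <- tolower(vapply(kids, `[[`, "", "name"))
    hit <- which(nms == tolower(seg))
    if (!length(hit)) break
    node <- kids[[hit[1]]]
    kids <- node$children
    depth <- depth + 1L
  }
  if (depth == n) return(list(kind = "exact", depth = depth))
  if (depth == n - 1L && !is.null(node)) {
    kid_names <- vapply(node$children, `[[`, "", "name")
    if ("#" %in% kid_names) return(list(kind = "valueMatch", depth = depth))
  }
  if (depth >= 1L &&
      (length(node$children) == 0L || isTRUE(node$attrs$extensionAllowed))) {
    return(list(kind = "extension", depth = depth))
  }
  list(kind = "miss", depth = depth)
}

# --- independent single-pass delimiter scanner ------------------------------
# Counts top-level elements and, per parenthesized span, tags per clause,
# using nothing but character arithmetic.
oracle_scan <- function(text) {
  ch <- strsplit(text, "")[[1]]
  depth <- cumsum((ch == "(") - c(0, (ch == ")")[-length(ch)]))
  n_top <- sum(ch == "," & depth == 0) + 1L
  opens <- which(ch == "(")
  closes <- which(ch == ")")
  groups <- lapply(seq_along(opens), function(g) {
    span <- ch[(opens[g] + 1L):(closes[g] - 1L)]
    clause_sizes <- vapply(
      strsplit(paste(span, collapse = ""), "~", fixed = TRUE)[[1]],
      function(cl) sum(strsplit(cl, "")[[1]] == ",") + 1L, 0L,
      USE.NAMES = FALSE)
    clause_sizes
  })
  list(n_top_elements = n_top, n_groups = length(opens), groups = groups)
}

# --- independent prefix-match oracle ----------------------------------------
oracle_prefix_match <- function(tag_text, prefix_text) {
  t <- tolower(strsplit(sub("^/", "", tag_text), "/", fixed = TRUE)[[1]])
  p <- tolower(strsplit(sub("^/", "", prefix_text), "/", fixed = TRUE)[[1]])
  length(p) <= length(t) && all(p == t[seq_along(p)])
}

# --- random HED string generator for property tests -------------------------
fx_tag_pool <- c(
  "/Event/Category/Experimental stimulus", "/Event/Label/Thing",
  "/Item/Object/Person", "/Item/Object/Animal/Fish",
  "/Item/2D shape/Ellipse/Circle", "/Attribute/Visual/Color/Red",
  "/Attribute/Location/Screen/Left", "/Action/Type/Eat",
  "/Participant/Effect/Cognitive/Target", "/Sensory presentation/Visual",
  "/Paradigm/Driving", "/Custom/Lab specific")

random_hed_text <- function() {
  n_el <- sample(1:4, 1)
  els <- vapply(seq_len(n_el), function(i) {
    if (runif(1) < 0.3) {
      n_cl <- sample(1:3, 1)
      cls <- vapply(seq_len(n_cl), function(j) {
        paste(sample(fx_tag_pool, sample(1:2, 1)), collapse = ", ")
      }, "")
      paste0("(", paste(cls, collapse = " ~ "), ")")
    } else {
      sample(fx_tag_pool, 1)
    }
  }, "")
  paste(els, collapse = ", ")
}
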