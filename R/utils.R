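# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All generators route through this so
# they are pure functions of their arguments.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

trim <- function(x) gsub("^[ \t]+|[ \t]+$", "", x)

# Split a tag path into segments; leading '/' optional, trailing '/' ignored.
split_tag_path <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  segs <- trim(segs)
  segs[nzchar(segs)]
}

join_tag_path <- function(segments) {
  paste0("/", paste(segments, collapse = "/"))
}

# Regex for a plain decimal / scientific number.
.num_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

is_number_text <- function(x) grepl(.num_re, trim(x))

# Read input that may be a file path, a single string with newlines, or a
# character vector of lines.
read_lines_any <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

# Split one TSV line into fields, preserving trailing empty fields (which
# strsplit drops).
split_fields <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  n <- nchar(gsub("[^\t]", "", line)) + 1L
  length(parts) <- n
  parts[is.na(parts)] <- ""
  parts
}

stop_hed <- function(class, message, ...) {
  stop(structure(
    class = c(class, "hed_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Deterministic case-insensitive ordering with a case-sensitive tiebreak.
ci_order <- function(x) {
  order(tolower(x), x, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
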