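# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical whitespace normalization for labels: trim + collapse runs.
norm_ws <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

# Case-insensitive comparison key. Labels are stored in canonical
# (first-declared) form but always compared case-insensitively.
label_key <- function(x) {
  tolower(norm_ws(x))
}

abort_provdash <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "provdash_error"), ...)
}

# Nearest lexical matches for "did you mean" errors.
nearest_matches <- function(x, candidates, n = 3L) {
  if (length(candidates) == 0L) return(character())
  d <- utils::adist(label_key(x), label_key(candidates))[1L, ]
  candidates[order(d)][seq_len(min(n, length(candidates)))]
}

# Deterministic case-folded lexicographic order, independent of locale.
cfold_sort <- function(x) {
  x[order(label_key(x), x, method = "radix")]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

utc_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
}
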