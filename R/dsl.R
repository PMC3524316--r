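# Text DSL for query patterns, used by the CLI and by saved-query files:
#
#   <Class>='<value>' (AND|OR) <Class>='<value>' ...
#
# Class names containing spaces are double-quoted; values are single-quoted
# with backslash escaping. Connectives are the binary AND / OR, folded left
# to right without precedence.

#' Construct a query pattern
#'
#' A query pattern is an ordered list of equality conditions joined by
#' binary AND/OR connectives. Mixed chains carry no operator precedence:
#' they are folded left to right, `((c1 op1 c2) op2 c3) ...`, matching the
#' order in which a query builder appends conditions.
#'
#' @param conditions Data frame with columns `class` and `value` (and
#'   optionally `operator`, which must currently be `"="`). `value` may be
#'   `NA` for a pending condition slot (see [propagate()]).
#' @param connectives Character vector of `"AND"` / `"OR"`, one fewer than
#'   the number of conditions.
#' @return A `provdash_pattern` object.
#' @export
query_pattern <- function(conditions = NULL, connectives = character()) {
  conditions <- tibble::as_tibble(
    conditions %||% tibble::tibble(class = character(), operator = character(), value = character())
  )
  if (!("operator" %in% names(conditions))) {
    conditions$operator <- rep("=", nrow(conditions))
  }
  if (!all(c("class", "value") %in% names(conditions))) {
    abort_provdash("`conditions` needs columns `class` and `value`.", "provdash_parse_error")
  }
  conditions <- conditions[, c("class", "operator", "value")]
  conditions$class <- norm_ws(conditions$class)
  conditions$value <- ifelse(is.na(conditions$value), NA_character_, norm_ws(conditions$value))
  if (any(conditions$operator != "=")) {
    abort_provdash("Only the '=' operator is supported.", "provdash_parse_error")
  }
  connectives <- toupper(connectives)
  if (!all(connectives %in% c("AND", "OR"))) {
    abort_provdash("Connectives must be 'AND' or 'OR'.", "provdash_parse_error")
  }
  n <- nrow(conditions)
  if (length(connectives) != max(n - 1L, 0L)) {
    abort_provdash(
      sprintf("Pattern with %d condition(s) needs %d connective(s), got %d.",
              n, max(n - 1L, 0L), length(connectives)),
      "provdash_parse_error"
    )
  }
  structure(list(conditions = conditions, connectives = unname(connectives)),
            class = "provdash_pattern")
}

#' @export
print.provdash_pattern <- function(x, ...) {
  cat("<provdash_pattern> ", if (nrow(x$conditions) == 0L) "(empty)" else render_dsl(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.provdash_pattern <- function(x, ...) render_dsl(x)

dsl_error <- function(text, pos, message) {
  caret <- paste0(strrep(" ", pos - 1L), "^")
  abort_provdash(
    sprintf("Query parse error at position %d: %s\n  %s\n  %s", pos, message, text, caret),
    "provdash_parse_error"
  )
}

# Tokenize a DSL string into class / '=' / value / connective tokens with
# 1-based positions for caret-annotated errors.
dsl_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  read_quoted <- function(i, quote) {
    j <- i + 1L
    out <- character()
    while (j <= n) {
      ch <- substr(text, j, j)
      if (ch == "\\") {
        out <- c(out, substr(text, j + 1L, j + 1L))
        j <- j + 2L
      } else if (ch == quote) {
        return(list(value = paste(out, collapse = ""), next_i = j + 1L))
      } else {
        out <- c(out, ch)
        j <- j + 1L
      }
    }
    dsl_error(text, i, sprintf("unterminated %s-quoted token", quote))
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "=") {
      tokens[[length(tokens) + 1L]] <- list(type = "eq", value = "=", pos = i)
      i <- i + 1L
      next
    }
    if (ch == '"' || ch == "'") {
      q <- read_quoted(i, ch)
      tokens[[length(tokens) + 1L]] <- list(
        type = if (ch == '"') "dquoted" else "squoted", value = q$value, pos = i
      )
      i <- q$next_i
      next
    }
    m <- regexpr("^[^[:space:]='\"]+", substr(text, i, n))
    word <- regmatches(substr(text, i, n), m)
    tokens[[length(tokens) + 1L]] <- list(type = "word", value = word, pos = i)
    i <- i + attr(m, "match.length")
  }
  tokens
}

#' Parse / render the query-pattern DSL
#'
#' `parse_dsl()` turns a DSL string such as
#' `"Cell line"='HCT116' AND Organism='Homo Sapiens'` into a
#' [query_pattern()]; `render_dsl()` is its inverse, and
#' `parse_dsl(render_dsl(p))` reproduces `p` exactly. Syntax errors carry a
#' caret-annotated message naming the offending position.
#'
#' @param text A DSL string. The empty string parses to the empty pattern.
#' @return `parse_dsl()`: a `provdash_pattern`. `render_dsl()`: a string.
#' @export
parse_dsl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- dsl_tokenize(text)
  if (length(tokens) == 0L) return(query_pattern())
  conds <- list()
  conns <- character()
  i <- 1L
  expect <- function(j, what) {
    if (j > length(tokens)) {
      dsl_error(text, nchar(text) + 1L, sprintf("expected %s but input ended", what))
    }
    tokens[[j]]
  }
  repeat {
    cls_tok <- expect(i, "a class name")
    if (!(cls_tok$type %in% c("word", "dquoted"))) {
      dsl_error(text, cls_tok$pos, "expected a class name (bare word or double-quoted)")
    }
    eq_tok <- expect(i + 1L, "'='")
    if (eq_tok$type != "eq") dsl_error(text, eq_tok$pos, "expected '=' after the class name")
    val_tok <- expect(i + 2L, "a single-quoted value")
    if (val_tok$type != "squoted") {
      dsl_error(text, val_tok$pos, "expected a single-quoted value after '='")
    }
    conds[[length(conds) + 1L]] <- tibble::tibble(
      class = cls_tok$value, operator = "=", value = val_tok$value
    )
    i <- i + 3L
    if (i > length(tokens)) break
    conn_tok <- tokens[[i]]
    if (!(conn_tok$type == "word" && toupper(conn_tok$value) %in% c("AND", "OR"))) {
      dsl_error(text, conn_tok$pos, "expected the connective AND or OR")
    }
    conns <- c(conns, toupper(conn_tok$value))
    i <- i + 1L
  }
  query_pattern(dplyr::bind_rows(conds), conns)
}

#' @rdname parse_dsl
#' @param p A `provdash_pattern`.
#' @export
render_dsl <- function(p) {
  stopifnot(inherits(p, "provdash_pattern"))
  n <- nrow(p$conditions)
  if (n == 0L) return("")
  quote_class <- function(x) {
    if (grepl("^[A-Za-z0-9_.-]+$", x)) x
    else paste0('"', gsub('"', '\\"', gsub("\\", "\\\\", x, fixed = TRUE), fixed = TRUE), '"')
  }
  quote_value <- function(x) {
    if (is.na(x)) return("''")
    paste0("'", gsub("'", "\\'", gsub("\\", "\\\\", x, fixed = TRUE), fixed = TRUE), "'")
  }
  parts <- character()
  for (i in seq_len(n)) {
    parts <- c(parts, sprintf("%s=%s", quote_class(p$conditions$class[i]),
                              quote_value(p$conditions$value[i])))
    if (i < n) parts <- c(parts, p$connectives[i])
  }
  paste(parts, collapse = " ")
}
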