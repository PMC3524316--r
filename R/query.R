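# Boolean query engine over the mapped store. Two independent execution
# routes exist on purpose: evaluate() folds per-condition truth vectors left
# to right in memory, while translate() emits a parameterized SQL-style
# query whose WHERE clause execute_translated() parses and evaluates
# recursively. Tests hold the two routes (plus a per-record oracle) to
# identical results.

# Match vector of one condition against the store (case-insensitive).
condition_matches <- function(s, class_name, value) {
  col <- mapped_column(store_config(s), class_name)
  if (!(col %in% names(s$experiments))) {
    abort_provdash(
      sprintf("Mapped column '%s' for class '%s' is absent from the store.", col, class_name),
      "provdash_translation_error"
    )
  }
  if (is.na(value)) {
    abort_provdash(
      sprintf("Condition on '%s' has no value; fill or drop the pending slot before evaluating.",
              class_name),
      "provdash_translation_error"
    )
  }
  label_key(s$experiments[[col]]) == label_key(value)
}

# The store carries its mapping; wrap it in a config so the same resolution
# path (and the same translation errors) serve both evaluate and translate.
store_config <- function(s) {
  data_source_config("store", "memory", s$mapping)
}

#' Evaluate a query pattern against a store
#'
#' An experiment matches when the left-to-right fold of its per-condition
#' truth values under the pattern's connectives is true:
#' `((c1 op1 c2) op2 c3) ...` with no operator precedence. The empty
#' pattern matches everything. Matches are grouped per project, ordered by
#' project id.
#'
#' @param p A [query_pattern()].
#' @param s A `provdash_store`.
#' @return A `provdash_results` object: list with `groups` (tibble
#'   `project_id`, `project_name`, `n`, and a list-column `experiments` of
#'   matching rows) and `total`, the overall match count.
#' @export
evaluate <- function(p, s) {
  stopifnot(inherits(p, "provdash_pattern"), inherits(s, "provdash_store"))
  n <- nrow(s$experiments)
  conds <- p$conditions
  if (nrow(conds) == 0L) {
    acc <- rep(TRUE, n)
  } else {
    # resolve every class before touching record values, so unmapped
    # classes fail identically for empty and non-empty stores
    for (i in seq_len(nrow(conds))) mapped_column(store_config(s), conds$class[i])
    acc <- condition_matches(s, conds$class[1], conds$value[1])
    for (i in seq_len(nrow(conds))[-1]) {
      v <- condition_matches(s, conds$class[i], conds$value[i])
      acc <- if (p$connectives[i - 1L] == "AND") acc & v else acc | v
    }
  }
  group_results(s, acc)
}

group_results <- function(s, match_vector) {
  hits <- s$experiments[match_vector, , drop = FALSE]
  if (nrow(hits) == 0L) {
    groups <- tibble::tibble(
      project_id = character(), project_name = character(), n = integer(),
      experiments = list()
    )
    # keep the experiment columns visible through tidy() even with no rows
    groups$experiments <- vctrs::list_of(.ptype = hits[0, setdiff(names(hits), "project_id")])
    return(structure(list(groups = groups, total = 0L), class = "provdash_results"))
  }
  groups <- hits |>
    dplyr::group_by(.data$project_id) |>
    tidyr::nest(experiments = !"project_id") |>
    dplyr::ungroup() |>
    dplyr::left_join(s$projects, by = "project_id") |>
    dplyr::transmute(
      .data$project_id,
      project_name = .data$name,
      n = purrr::map_int(.data$experiments, nrow),
      .data$experiments
    ) |>
    dplyr::arrange(.data$project_id)
  structure(list(groups = groups, total = nrow(hits)), class = "provdash_results")
}

#' @export
print.provdash_results <- function(x, ...) {
  cat(sprintf("<provdash_results> %d matching experiment(s) in %d project(s)\n",
              x$total, nrow(x$groups)))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %s (%s): %d\n", x$groups$project_id[i], x$groups$project_name[i], x$groups$n[i]))
  }
  invisible(x)
}

#' @export
tidy.provdash_results <- function(x, ...) {
  out <- tidyr::unnest(x$groups[, c("project_id", "project_name", "experiments")],
                       "experiments")
  tibble::as_tibble(out)
}

#' @export
glance.provdash_results <- function(x, ...) {
  tibble::tibble(total = x$total, n_projects = nrow(x$groups))
}

#' @export
autoplot.provdash_results <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$project_id, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Project", y = "Matching experiments",
                  title = sprintf("Query matches by project (total %d)", object$total)) +
    ggplot2::theme_minimal()
}

#' Translate a query pattern to a parameterized store query
#'
#' Emits an SQL-style query whose WHERE clause is explicitly parenthesized
#' as the left-to-right fold `(((c1 op1 c2) op2 c3) ...)`; values are bound
#' parameters (`?` placeholders), never interpolated into the text, and
#' comparisons are wrapped in `LOWER()` on both sides to make the
#' case-insensitive semantics explicit in the emitted text.
#'
#' @param p A [query_pattern()].
#' @param cfg A `provdash_config` resolving each condition's class to a
#'   store column. Unmapped classes raise a translation error naming the
#'   class.
#' @return A `provdash_translated` object: list with `sql` (full SELECT),
#'   `clause` (the WHERE clause alone) and `params` (bound values in
#'   order).
#' @export
translate <- function(p, cfg) {
  stopifnot(inherits(p, "provdash_pattern"), inherits(cfg, "provdash_config"))
  conds <- p$conditions
  n <- nrow(conds)
  if (n == 0L) {
    clause <- "1 = 1"
    params <- character()
  } else {
    atoms <- vapply(seq_len(n), function(i) {
      sprintf("LOWER(%s) = LOWER(?)", mapped_column(cfg, conds$class[i]))
    }, "")
    clause <- atoms[1]
    for (i in seq_len(n)[-1]) {
      clause <- sprintf("(%s %s %s)", clause, p$connectives[i - 1L], atoms[i])
    }
    params <- conds$value
  }
  structure(
    list(
      sql = sprintf("SELECT experiment_id, project_id FROM experiments WHERE %s", clause),
      clause = clause,
      params = params
    ),
    class = "provdash_translated"
  )
}

#' @export
print.provdash_translated <- function(x, ...) {
  cat("<provdash_translated>\n  ", x$sql, "\n", sep = "")
  if (length(x$params) > 0L) {
    cat("  params: ", paste(sprintf("'%s'", x$params), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# --- independent execution route -------------------------------------------

# Recursive-descent parse of the emitted WHERE clause, evaluated vectorized
# against the store. Deliberately shares no code with evaluate().
#' Execute a translated query against a store
#'
#' Parses the parenthesized WHERE clause emitted by [translate()], binds the
#' parameters in order, and evaluates it vectorized over the store. This is
#' an execution route independent of [evaluate()]; the two must agree on
#' every pattern.
#'
#' @param tq A `provdash_translated`.
#' @param s A `provdash_store`.
#' @return A `provdash_results`, as for [evaluate()].
#' @export
execute_translated <- function(tq, s) {
  stopifnot(inherits(tq, "provdash_translated"), inherits(s, "provdash_store"))
  nrec <- nrow(s$experiments)
  clause <- tq$clause
  params <- tq$params
  pcursor <- 0L

  toks <- regmatches(clause, gregexpr("\\(|\\)|LOWER\\([A-Za-z0-9_?]+\\)|=|AND|OR|1", clause))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_expr <- function() {
    acc <- parse_atom()
    repeat {
      t <- peek()
      if (is.na(t) || !(t %in% c("AND", "OR"))) return(acc)
      op <- take()
      rhs <- parse_atom()
      acc <- if (op == "AND") acc & rhs else acc | rhs
    }
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) {
      abort_provdash("Malformed translated clause: unexpected end.", "provdash_internal_error")
    }
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) {
        abort_provdash("Malformed translated clause: missing ')'.", "provdash_internal_error")
      }
      return(e)
    }
    if (t == "1") {  # the vacuous '1 = 1' clause
      take()  # '='
      take()  # '1'
      return(rep(TRUE, nrec))
    }
    # LOWER(col) = LOWER(?)
    col <- sub("^LOWER\\(", "", sub("\\)$", "", t))
    if (!identical(take(), "=")) {
      abort_provdash("Malformed translated clause: expected '='.", "provdash_internal_error")
    }
    rhs <- take()
    if (!identical(rhs, "LOWER(?)")) {
      abort_provdash("Malformed translated clause: expected a bound parameter.", "provdash_internal_error")
    }
    pcursor <<- pcursor + 1L
    value <- params[[pcursor]]
    if (!(col %in% names(s$experiments))) {
      abort_provdash(sprintf("Translated query names unknown column '%s'.", col),
                     "provdash_translation_error")
    }
    tolower(norm_ws(s$experiments[[col]])) == tolower(norm_ws(value))
  }

  match_vector <- parse_expr()
  if (!is.na(peek())) {
    abort_provdash("Malformed translated clause: trailing tokens.", "provdash_internal_error")
  }
  group_results(s, match_vector)
}

#' Link-out URL for an experiment record
#'
#' Builds the deterministic URL under which the experiment's primary data
#' lives in the upstream data-management system (e.g. a LabKey server).
#' No network access is performed; this is a URL stub.
#'
#' @param e A one-row experiment data frame (or list) with `project_id` and
#'   `experiment_id`.
#' @param base_url Server base URL; the empty string yields a relative
#'   path.
#' @return A character URL `"<base>/project/<project_id>/experiment/<experiment_id>"`.
#' @export
link_out <- function(e, base_url = "") {
  base <- sub("/+$", "", base_url)
  path <- sprintf("project/%s/experiment/%s", e$project_id, e$experiment_id)
  if (nchar(base) == 0L) path else paste(base, path, sep = "/")
}
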