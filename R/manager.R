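# Saved-query catalog: named, dated, re-executable query patterns persisted
# in one human-readable YAML document. Writes go through a temp file and an
# atomic rename, so a crash can lose at most the in-flight save.

#' Open (or create) a saved-query catalog
#'
#' @param path Path of the catalog YAML file. A missing file yields an
#'   empty catalog; the file is created on first save.
#' @return A `provdash_catalog` object: list with `path` and `entries`, a
#'   tibble with columns `name`, `description`, `creator`, `created_at`,
#'   `updated_at` (ISO 8601 UTC) and `pattern` (DSL text).
#' @export
query_catalog <- function(path) {
  entries <- empty_entries()
  if (file.exists(path)) {
    doc <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) {
        abort_provdash(sprintf("Catalog file %s is not valid YAML: %s", path, conditionMessage(e)),
                       "provdash_config_error")
      }
    )
    entries <- purrr::map_dfr(doc$entries, function(e) {
      tibble::tibble(
        name = e$name, description = e$description %||% "",
        creator = e$creator %||% "", created_at = e$created_at,
        updated_at = e$updated_at, pattern = e$pattern
      )
    })
    if (nrow(entries) == 0L) entries <- empty_entries()
  }
  structure(list(path = path, entries = entries), class = "provdash_catalog")
}

empty_entries <- function() {
  tibble::tibble(
    name = character(), description = character(), creator = character(),
    created_at = character(), updated_at = character(), pattern = character()
  )
}

write_catalog <- function(cat) {
  doc <- list(
    format_version = 1L,
    entries = purrr::pmap(cat$entries, function(name, description, creator,
                                                created_at, updated_at, pattern) {
      list(name = name, description = description, creator = creator,
           created_at = created_at, updated_at = updated_at, pattern = pattern)
    })
  )
  tmp <- paste0(cat$path, ".tmp")
  yaml::write_yaml(doc, tmp)
  if (!file.rename(tmp, cat$path)) {
    abort_provdash(sprintf("Cannot write catalog file %s.", cat$path), "provdash_io_error")
  }
  invisible(cat)
}

#' @export
print.provdash_catalog <- function(x, ...) {
  cat(sprintf("<provdash_catalog> %d saved quer%s at %s\n",
              nrow(x$entries), if (nrow(x$entries) == 1L) "y" else "ies", x$path))
  invisible(x)
}

#' Save a named query into the catalog
#'
#' The pattern is parsed before anything is persisted, so unparsable text
#' never reaches the catalog. Saving under an existing name updates the
#' pattern, description and creator and bumps `updated_at` (strictly; the
#' original `created_at` is preserved). The catalog file is rewritten
#' atomically.
#'
#' @param cat A [query_catalog()].
#' @param name Unique, non-empty query name.
#' @param pattern A `provdash_pattern` or a DSL string.
#' @param description,creator Free-text metadata shown in listings.
#' @return The updated `provdash_catalog` (already persisted).
#' @export
save_query <- function(cat, name, pattern, description = "", creator = "") {
  stopifnot(inherits(cat, "provdash_catalog"))
  name <- norm_ws(name)
  if (is.na(name) || nchar(name) == 0L) {
    abort_provdash("A saved query needs a non-empty name.", "provdash_config_error")
  }
  dsl <- if (inherits(pattern, "provdash_pattern")) render_dsl(pattern) else pattern
  parse_dsl(dsl)  # reject unparsable patterns before persistence

  now <- utc_now()
  i <- match(name, cat$entries$name)
  if (is.na(i)) {
    cat$entries <- dplyr::bind_rows(cat$entries, tibble::tibble(
      name = name, description = description, creator = creator,
      created_at = now, updated_at = now, pattern = dsl
    ))
  } else {
    # updated_at must strictly increase even on sub-microsecond re-saves
    prev <- cat$entries$updated_at[i]
    if (now <= prev) {
      t <- as.POSIXct(prev, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC") + 1e-6
      now <- format(t, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
      if (now <= prev) now <- paste0(substr(prev, 1, nchar(prev) - 1L), "0Z")
    }
    cat$entries$pattern[i] <- dsl
    cat$entries$description[i] <- description
    cat$entries$creator[i] <- creator
    cat$entries$updated_at[i] <- now
  }
  write_catalog(cat)
}

#' List saved queries
#'
#' @param cat A [query_catalog()].
#' @return The catalog entries as a tibble, most recently updated first,
#'   ties broken by name.
#' @export
list_queries <- function(cat) {
  stopifnot(inherits(cat, "provdash_catalog"))
  e <- cat$entries
  e[order(e$updated_at, e$name, decreasing = c(TRUE, FALSE), method = "radix"), ]
}

#' Fetch one saved query by name
#'
#' @inheritParams list_queries
#' @param name Saved-query name.
#' @return A one-row tibble.
#' @export
get_query <- function(cat, name) {
  stopifnot(inherits(cat, "provdash_catalog"))
  i <- match(norm_ws(name), cat$entries$name)
  if (is.na(i)) {
    near <- nearest_matches(name, cat$entries$name)
    abort_provdash(
      sprintf("No saved query named '%s'.%s", name,
              if (length(near) > 0L) sprintf(" Did you mean: %s?", paste(near, collapse = ", ")) else ""),
      "provdash_lookup_error"
    )
  }
  cat$entries[i, ]
}

#' Delete a saved query
#'
#' @inheritParams get_query
#' @return The updated, persisted catalog.
#' @export
delete_query <- function(cat, name) {
  get_query(cat, name)  # lookup error if absent
  cat$entries <- cat$entries[cat$entries$name != norm_ws(name), ]
  write_catalog(cat)
}

#' Re-execute a saved query
#'
#' Parses the stored DSL text and evaluates it against the store at call
#' time; nothing is cached, so a regenerated store yields fresh results.
#'
#' @inheritParams get_query
#' @param s A `provdash_store`.
#' @return A `provdash_results`, as for [evaluate()].
#' @export
run_saved <- function(cat, name, s) {
  entry <- get_query(cat, name)
  evaluate(parse_dsl(entry$pattern), s)
}
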