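# Data-source configuration: the declared correspondence between ontology
# classes (facets) and columns of the experiment-metadata store. Mappings
# are curated by hand, so validation reports problems instead of failing.

#' Build a data-source configuration
#'
#' A data source is a store location plus an injective mapping from ontology
#' classes to store columns (wide-table model: one column per facet). Query
#' translation resolves every condition's class through this mapping.
#'
#' @param name Data-source label.
#' @param store_uri Location of the experiment-metadata store (a directory
#'   of delimited files, see [export_store()]).
#' @param mappings A data frame with columns `class` and `column`.
#' @return A `provdash_config` object.
#' @export
data_source_config <- function(name, store_uri, mappings) {
  mappings <- tibble::as_tibble(mappings)
  if (!all(c("class", "column") %in% names(mappings))) {
    abort_provdash("`mappings` needs columns `class` and `column`.", "provdash_config_error")
  }
  mappings$class <- norm_ws(mappings$class)
  mappings$column <- norm_ws(mappings$column)
  if (nrow(mappings) == 0L) {
    abort_provdash("A data source needs at least one class-to-column mapping.", "provdash_config_error")
  }
  dup_class <- duplicated(label_key(mappings$class))
  if (any(dup_class)) {
    abort_provdash(
      sprintf("Class(es) mapped more than once: %s",
              paste(unique(mappings$class[dup_class]), collapse = ", ")),
      "provdash_config_error"
    )
  }
  dup_col <- duplicated(mappings$column)
  if (any(dup_col)) {
    abort_provdash(
      sprintf("Mapping is not injective; column(s) used by several classes: %s",
              paste(unique(mappings$column[dup_col]), collapse = ", ")),
      "provdash_config_error"
    )
  }
  structure(
    list(name = name, store_uri = store_uri,
         mappings = mappings[, c("class", "column")]),
    class = "provdash_config"
  )
}

#' @export
print.provdash_config <- function(x, ...) {
  cat(sprintf("<provdash_config> '%s' (%d mappings) -> %s\n",
              x$name, nrow(x$mappings), x$store_uri))
  invisible(x)
}

#' Read or write a data-source configuration file
#'
#' The on-disk dialect is a small YAML document with keys `format_version`,
#' `name`, `store_uri` and `mappings` (a list of `{class, column}` pairs).
#'
#' @param path Path to a YAML configuration file.
#' @return `load_config()` returns a `provdash_config`; `save_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_provdash(sprintf("Config file not found: %s", path), "provdash_io_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort_provdash(sprintf("Config syntax error in %s: %s", path, conditionMessage(e)),
                     "provdash_config_error")
    }
  )
  for (key in c("name", "store_uri", "mappings")) {
    if (is.null(doc[[key]])) {
      abort_provdash(sprintf("Config %s: missing key '%s'.", path, key), "provdash_config_error")
    }
  }
  maps <- purrr::map_dfr(doc$mappings, function(m) {
    if (is.null(m$class) || is.null(m$column)) {
      abort_provdash(
        sprintf("Config %s: every entry under 'mappings' needs 'class' and 'column'.", path),
        "provdash_config_error"
      )
    }
    tibble::tibble(class = m$class, column = m$column)
  })
  data_source_config(doc$name, doc$store_uri, maps)
}

#' @rdname load_config
#' @param cfg A `provdash_config` object.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "provdash_config"))
  doc <- list(
    format_version = 1L,
    name = cfg$name,
    store_uri = cfg$store_uri,
    mappings = purrr::pmap(cfg$mappings, function(class, column) {
      list(class = class, column = column)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Validate a mapping against an ontology and a store schema
#'
#' Cross-checks the configured class-to-column mapping against the loaded
#' ontology and the store's column set. All problems are report rows, never
#' errors: mapped classes absent from the ontology (`missing_class`), mapped
#' columns absent from the store schema (`missing_column`), and ontology
#' classes that carry instances but have no mapping (`unmapped_facet`, a
#' warning-level entry since curated mappings are typically partial). An
#' empty report means every query over mapped classes can be translated.
#'
#' @param cfg A `provdash_config`.
#' @param o A [ontology()] object.
#' @param schema Character vector of store column identifiers.
#' @return A tibble with columns `kind`, `class`, `column`, `message`;
#'   zero rows when the mapping is fully usable.
#' @export
validate_mapping <- function(cfg, o, schema) {
  stopifnot(inherits(cfg, "provdash_config"), inherits(o, "provdash_ontology"))
  m <- cfg$mappings
  report <- tibble::tibble(
    kind = character(), class = character(), column = character(), message = character()
  )

  absent_class <- !(label_key(m$class) %in% label_key(o$classes$name))
  if (any(absent_class)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      kind = "missing_class",
      class = m$class[absent_class],
      column = m$column[absent_class],
      message = sprintf("Mapped class '%s' is not declared in the ontology.", m$class[absent_class])
    ))
  }
  absent_col <- !(m$column %in% schema)
  if (any(absent_col)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      kind = "missing_column",
      class = m$class[absent_col],
      column = m$column[absent_col],
      message = sprintf("Mapped column '%s' is not in the store schema.", m$column[absent_col])
    ))
  }
  with_instances <- unique(o$instances$class)
  unmapped <- with_instances[!(label_key(with_instances) %in% label_key(m$class))]
  if (length(unmapped) > 0L) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      kind = "unmapped_facet",
      class = unmapped,
      column = NA_character_,
      message = sprintf("Ontology class '%s' has instances but no column mapping.", unmapped)
    ))
  }
  report
}

# Resolve a condition class to its mapped store column (case-insensitive on
# the class side). Raises a translation error before any store access.
mapped_column <- function(cfg, class_name) {
  i <- match(label_key(class_name), label_key(cfg$mappings$class))
  if (is.na(i)) {
    abort_provdash(
      sprintf("Class '%s' has no column mapping in data source '%s'.", class_name, cfg$name),
      "provdash_translation_error"
    )
  }
  cfg$mappings$column[i]
}
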