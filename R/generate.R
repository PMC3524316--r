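# Seeded synthetic experiment-metadata store. Emulates the corpus of a
# proteomics core running AP-MS and shotgun expression workflows across a
# handful of projects, so the query engine is testable end to end without
# institutional data.

#' Specification for the synthetic store generator
#'
#' @param n_projects Number of projects (default 7). Experiments are spread
#'   over projects by a seeded weighted draw, so project sizes are uneven,
#'   which exercises per-project result grouping.
#' @param n_experiments Number of experiment records (default 1000).
#' @param seed Integer random seed; [generate_store()] is a pure function of
#'   `(spec, ontology, config)`.
#' @param vocabularies Named list class -> instance labels to draw attribute
#'   values from; defaults to [default_vocabularies()]. Every label must be
#'   declared in the ontology.
#' @param hard_constraints Relation-shaped data frame (columns
#'   `subject_class`, `subject`, `predicate`, `object_class`, `object`) that
#'   every generated record must satisfy: whenever a record's
#'   `subject_class` attribute equals `subject`, its `object_class`
#'   attribute must be one of the asserted objects for that subject.
#'   `NULL` (the default) derives the constraints from the ontology's own
#'   instance-level relations.
#' @param files_per_experiment Number of data files attached to each
#'   experiment record (default 3).
#' @return A `provdash_generator_spec` object.
#' @export
generator_spec <- function(n_projects = 7L, n_experiments = 1000L, seed = 42L,
                           vocabularies = default_vocabularies(),
                           hard_constraints = NULL,
                           files_per_experiment = 3L) {
  if (!is_count(n_projects)) {
    abort_provdash("`n_projects` must be a positive integer.", "provdash_generation_error")
  }
  if (!is_count(n_experiments)) {
    abort_provdash("`n_experiments` must be a positive integer.", "provdash_generation_error")
  }
  if (!is_count(files_per_experiment)) {
    abort_provdash("`files_per_experiment` must be a positive integer.", "provdash_generation_error")
  }
  structure(
    list(
      n_projects = as.integer(n_projects),
      n_experiments = as.integer(n_experiments),
      seed = as.integer(seed),
      vocabularies = vocabularies,
      hard_constraints = if (!is.null(hard_constraints)) tibble::as_tibble(hard_constraints),
      files_per_experiment = as.integer(files_per_experiment)
    ),
    class = "provdash_generator_spec"
  )
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Generate a synthetic experiment-metadata store
#'
#' Draws `n_experiments` experiment records across `n_projects` projects.
#' Attribute values are sampled from the spec's vocabularies, then every
#' hard constraint is enforced (e.g. a record with bait gene EPHB2 always
#' has cell line HCT116), and finally a deterministic coverage patch
#' guarantees that every vocabulary value occurs in at least one record —
#' patched rows are chosen so no constraint is re-violated. The result is a
#' pure function of `(spec, o, cfg)`: the same seed reproduces the store
#' bit for bit.
#'
#' @param spec A [generator_spec()].
#' @param o A [ontology()] the vocabularies and constraints are validated
#'   against.
#' @param cfg A `provdash_config` naming the store column for each facet
#'   class; defaults to [default_config()].
#' @return A `provdash_store`: list with tibbles `projects`
#'   (`project_id`, `name`) and `experiments` (`experiment_id`,
#'   `project_id`, one column per mapped facet, and a `files` list-column),
#'   plus the active `mapping`.
#' @export
generate_store <- function(spec, o, cfg = default_config()) {
  stopifnot(inherits(spec, "provdash_generator_spec"), inherits(o, "provdash_ontology"))
  vocab <- spec$vocabularies

  # validate: every vocabulary label is a declared instance of its class
  for (cls in names(vocab)) {
    declared <- instances_of(o, cls)$label
    missing <- vocab[[cls]][!(label_key(vocab[[cls]]) %in% label_key(declared))]
    if (length(missing) > 0L) {
      abort_provdash(
        sprintf("Vocabulary value(s) for '%s' not declared in the ontology: %s",
                cls, paste(missing, collapse = ", ")),
        "provdash_generation_error"
      )
    }
  }
  constraints <- spec$hard_constraints %||% o$relations
  if (nrow(constraints) > 0L) {
    for (i in seq_len(nrow(constraints))) {
      resolve_instance(o, constraints$subject[i], constraints$subject_class[i])
      resolve_instance(o, constraints$object[i], constraints$object_class[i])
    }
  }
  # constraints only bind for classes the generator actually draws
  constraints <- constraints[
    label_key(constraints$subject_class) %in% label_key(names(vocab)) &
      label_key(constraints$object_class) %in% label_key(names(vocab)), , drop = FALSE]
  # unsatisfiable: one subject forced into two disjoint singleton objects is
  # impossible under the grouped-membership semantics, but a subject whose
  # asserted object is absent from the vocabulary is a conflict.
  if (nrow(constraints) > 0L) {
    canon_class <- function(x) names(vocab)[match(label_key(x), label_key(names(vocab)))]
    constraints$subject_class <- canon_class(constraints$subject_class)
    constraints$object_class <- canon_class(constraints$object_class)
    ok_obj <- purrr::map_lgl(seq_len(nrow(constraints)), function(i) {
      label_key(constraints$object[i]) %in% label_key(vocab[[constraints$object_class[i]]])
    })
    if (!all(ok_obj)) {
      b <- constraints[!ok_obj, ][1, ]
      abort_provdash(
        sprintf("Unsatisfiable constraint: '%s'='%s' requires '%s'='%s', which is not in the vocabulary.",
                b$subject_class, b$subject, b$object_class, b$object),
        "provdash_generation_error"
      )
    }
  }

  n <- spec$n_experiments
  k <- spec$n_projects
  with_rng(spec$seed, {
    projects <- tibble::tibble(
      project_id = sprintf("P%d", seq_len(k)),
      name = sprintf("Project %02d", seq_len(k))
    )
    # uneven project sizes: weighted draw, but every project gets >= 1
    # experiment when n >= k
    weights <- stats::runif(k, min = 0.2, max = 1)
    assignment <- c(
      seq_len(min(k, n)),
      if (n > k) sample.int(k, n - k, replace = TRUE, prob = weights)
    )
    width <- max(4L, nchar(as.character(n)))
    ex <- tibble::tibble(
      experiment_id = sprintf("E%0*d", width, seq_len(n)),
      project_id = projects$project_id[assignment]
    )
    for (cls in names(vocab)) {
      col <- mapped_column(cfg, cls)
      ex[[col]] <- vocab[[cls]][sample.int(length(vocab[[cls]]), n, replace = TRUE)]
    }

    enforce <- function(ex) {
      if (nrow(constraints) == 0L) return(ex)
      groups <- split(constraints, paste(constraints$subject_class, label_key(constraints$subject),
                                         constraints$object_class, sep = "\r"))
      for (g in groups) {
        scol <- mapped_column(cfg, g$subject_class[1])
        ocol <- mapped_column(cfg, g$object_class[1])
        allowed <- unique(g$object)
        hit <- label_key(ex[[scol]]) == label_key(g$subject[1])
        bad <- hit & !(label_key(ex[[ocol]]) %in% label_key(allowed))
        if (any(bad)) {
          ex[[ocol]][bad] <- allowed[sample.int(length(allowed), sum(bad), replace = TRUE)]
        }
      }
      ex
    }
    ex <- enforce(ex)

    # Coverage patch: every vocabulary value must appear in >= 1 record so
    # downstream completeness checks are non-vacuous. Subject-side classes
    # first (their objects are then re-enforced), then the rest on rows
    # where no constraint fires.
    subject_classes <- unique(constraints$subject_class)
    patch_order <- c(
      intersect(names(vocab), subject_classes),
      setdiff(names(vocab), subject_classes)
    )
    row_ok <- function(ex, row, cls, value) {
      if (nrow(constraints) == 0L) return(TRUE)
      for (j in seq_len(nrow(constraints))) {
        sc <- constraints$subject_class[j]; oc <- constraints$object_class[j]
        if (label_key(oc) != label_key(cls)) next
        scol <- mapped_column(cfg, sc)
        if (label_key(ex[[scol]][row]) != label_key(constraints$subject[j])) next
        allowed <- constraints$object[label_key(constraints$subject_class) == label_key(sc) &
                                        label_key(constraints$subject) == label_key(constraints$subject[j]) &
                                        label_key(constraints$object_class) == label_key(oc)]
        if (!(label_key(value) %in% label_key(allowed))) return(FALSE)
      }
      TRUE
    }
    cursor <- 1L
    for (cls in patch_order) {
      col <- mapped_column(cfg, cls)
      missing <- vocab[[cls]][!(label_key(vocab[[cls]]) %in% label_key(ex[[col]]))]
      for (value in missing) {
        placed <- FALSE
        for (step in seq_len(n)) {
          row <- ((cursor - 1L + step - 1L) %% n) + 1L
          if (row_ok(ex, row, cls, value)) {
            ex[[col]][row] <- value
            cursor <- row + 1L
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort_provdash(
            sprintf("Cannot place vocabulary value '%s' for '%s' without violating a constraint.",
                    value, cls),
            "provdash_generation_error"
          )
        }
      }
      if (cls %in% subject_classes) ex <- enforce(ex)
    }
    # after all patching, every constraint must hold and coverage must be complete
    for (cls in names(vocab)) {
      col <- mapped_column(cfg, cls)
      still_missing <- vocab[[cls]][!(label_key(vocab[[cls]]) %in% label_key(ex[[col]]))]
      if (length(still_missing) > 0L) {
        abort_provdash(
          sprintf("Coverage patching failed for '%s': %s absent.", cls,
                  paste(still_missing, collapse = ", ")),
          "provdash_generation_error"
        )
      }
    }

    ex$files <- purrr::map2(ex$project_id, ex$experiment_id, function(p, e) {
      sprintf("%s_%s_run%02d.raw", p, e, seq_len(spec$files_per_experiment))
    })

    new_store(projects, ex, cfg$mappings)
  })
}

new_store <- function(projects, experiments, mapping) {
  structure(
    list(projects = projects, experiments = experiments,
         mapping = tibble::as_tibble(mapping)),
    class = "provdash_store"
  )
}

#' @export
print.provdash_store <- function(x, ...) {
  cat(sprintf("<provdash_store> %d experiments in %d projects (%d mapped facets)\n",
              nrow(x$experiments), nrow(x$projects), nrow(x$mapping)))
  invisible(x)
}

#' @export
glance.provdash_store <- function(x, ...) {
  tibble::tibble(
    n_experiments = nrow(x$experiments),
    n_projects = nrow(x$projects),
    n_facets = nrow(x$mapping)
  )
}

#' Export / import an experiment-metadata store
#'
#' `export_store()` writes the store to a directory as tab-delimited text:
#' `projects.tsv`, `experiments.tsv` (the relational tables the query engine
#' consumes; the `files` list-column is serialized `;`-separated),
#' `mapping.tsv` (the facet-to-column map), and `store_flat.tsv`, a
#' denormalized single-table dump with project names joined in.
#' `import_store()` reads the directory back; the round trip is lossless.
#'
#' @param s A `provdash_store`.
#' @param path Directory to write to (created if needed).
#' @return `export_store()` returns `path` invisibly; `import_store()`
#'   returns a `provdash_store`.
#' @export
export_store <- function(s, path) {
  stopifnot(inherits(s, "provdash_store"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort_provdash(sprintf("Cannot create store directory: %s", path), "provdash_io_error")
  }
  ex <- s$experiments
  ex$files <- vapply(ex$files, paste, "", collapse = ";")
  readr::write_tsv(s$projects, file.path(path, "projects.tsv"), progress = FALSE)
  readr::write_tsv(ex, file.path(path, "experiments.tsv"), progress = FALSE)
  readr::write_tsv(s$mapping, file.path(path, "mapping.tsv"), progress = FALSE)
  flat <- dplyr::left_join(ex, s$projects, by = "project_id")
  readr::write_tsv(flat, file.path(path, "store_flat.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname export_store
#' @export
import_store <- function(path) {
  for (f in c("projects.tsv", "experiments.tsv", "mapping.tsv")) {
    if (!file.exists(file.path(path, f))) {
      abort_provdash(sprintf("Store directory %s is missing %s.", path, f), "provdash_io_error")
    }
  }
  ct <- readr::cols(.default = readr::col_character())
  projects <- readr::read_tsv(file.path(path, "projects.tsv"), col_types = ct, progress = FALSE)
  ex <- readr::read_tsv(file.path(path, "experiments.tsv"), col_types = ct, progress = FALSE)
  mapping <- readr::read_tsv(file.path(path, "mapping.tsv"), col_types = ct, progress = FALSE)
  ex$files <- strsplit(ex$files, ";", fixed = TRUE)
  new_store(projects, ex, mapping)
}
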