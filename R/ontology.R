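#' Provenance ontology container
#'
#' An experiment-metadata ontology extends the three W3C PROV-O core classes
#' (`prov:Activity`, `prov:Entity`, `prov:Agent`) with domain classes such as
#' "Cell line" or "Bait gene". Each domain class carries a set of instance
#' values (the admissible facet values, e.g. `HCT116`), and instances may be
#' linked by typed instance-level relations drawn from a controlled PROV
#' vocabulary (`hadRole`, `used`, `wasAttributedTo`). Relations encode domain
#' constraints such as "the bait gene EPHB2 is only ever used in cell line
#' HCT116", which drive smart filtering and constraint propagation in the
#' query builder.
#'
#' @param classes A data frame with columns `name` (unique class label) and
#'   `parent` (parent class label, or `NA` for the three PROV-O roots). The
#'   roots `Activity`, `Entity` and `Agent` are always present and are added
#'   automatically when missing.
#' @param instances A data frame with columns `class` (owning class name) and
#'   `label` (instance value). `(class, label)` pairs must be unique
#'   case-insensitively.
#' @param relations A data frame with columns `subject_class`, `subject`,
#'   `predicate`, `object_class`, `object`; subject and object must resolve
#'   to declared instances and the predicate must be one of
#'   [prov_predicates()].
#'
#' @return An object of class `provdash_ontology`: a list of three tibbles
#'   (`classes`, `instances`, `relations`). `classes` gains a `prov_core`
#'   column naming which of the three roots each class transitively extends.
#' @examples
#' o <- ontology(
#'   classes   = data.frame(name = "Bait Type", parent = "Entity"),
#'   instances = data.frame(class = "Bait Type", label = c("Tagged", "Endogenous"))
#' )
#' instances_of(o, "Bait Type")
#' @export
ontology <- function(classes = NULL, instances = NULL, relations = NULL) {
  classes <- tibble::as_tibble(classes %||% tibble::tibble(name = character(), parent = character()))
  instances <- tibble::as_tibble(instances %||% tibble::tibble(class = character(), label = character()))
  relations <- tibble::as_tibble(relations %||% empty_relations())
  if (!all(c("name", "parent") %in% names(classes))) {
    abort_provdash("`classes` needs columns `name` and `parent`.", "provdash_validation_error")
  }
  if (!all(c("class", "label") %in% names(instances))) {
    abort_provdash("`instances` needs columns `class` and `label`.", "provdash_validation_error")
  }
  rel_cols <- c("subject_class", "subject", "predicate", "object_class", "object")
  if (!all(rel_cols %in% names(relations))) {
    abort_provdash(
      "`relations` needs columns subject_class, subject, predicate, object_class, object.",
      "provdash_validation_error"
    )
  }

  classes$name <- unname(norm_ws(classes$name))
  classes$parent <- unname(norm_ws(classes$parent))
  instances$class <- unname(norm_ws(instances$class))
  instances$label <- unname(norm_ws(instances$label))
  for (col in rel_cols) relations[[col]] <- unname(norm_ws(relations[[col]]))

  # Roots are implicit: always part of every ontology.
  missing_roots <- setdiff(prov_roots(), classes$name)
  if (length(missing_roots) > 0L) {
    classes <- dplyr::bind_rows(
      tibble::tibble(name = missing_roots, parent = NA_character_),
      classes
    )
  }
  classes <- dplyr::distinct(classes[, c("name", "parent")])

  o <- structure(
    list(classes = classes, instances = instances[, c("class", "label")],
         relations = relations[, rel_cols]),
    class = "provdash_ontology"
  )
  validate_ontology(o)
}

#' @rdname ontology
#' @export
prov_roots <- function() c("Activity", "Entity", "Agent")

#' @rdname ontology
#' @export
prov_predicates <- function() c("hadRole", "used", "wasAttributedTo")

empty_relations <- function() {
  tibble::tibble(
    subject_class = character(), subject = character(), predicate = character(),
    object_class = character(), object = character()
  )
}

# Closed-world validation: every reference must resolve internally, the
# class graph must be a forest rooted at the three PROV-O cores, and labels
# must be unique under case folding.
validate_ontology <- function(o) {
  cl <- o$classes
  dup <- duplicated(label_key(cl$name))
  if (any(dup)) {
    abort_provdash(
      sprintf("Duplicate class name(s): %s", paste(unique(cl$name[dup]), collapse = ", ")),
      "provdash_validation_error"
    )
  }

  roots <- prov_roots()
  key <- label_key(cl$name)
  parent_key <- label_key(cl$parent)
  is_root <- cl$name %in% roots
  if (any(is_root & !is.na(cl$parent))) {
    abort_provdash("PROV-O core roots must not have a parent.", "provdash_validation_error")
  }
  bad_parent <- !is_root & (is.na(parent_key) | !(parent_key %in% key))
  if (any(bad_parent)) {
    abort_provdash(
      sprintf(
        "Class(es) with missing or undeclared parent: %s",
        paste(cl$name[bad_parent], collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }

  # Walk each class up to a root; cycles or orphans are validation errors.
  parent_of <- stats::setNames(parent_key, key)
  core <- character(length(key))
  for (i in seq_along(key)) {
    seen <- character()
    k <- key[i]
    while (!(k %in% label_key(roots))) {
      if (k %in% seen) {
        abort_provdash(
          sprintf("Cycle in class hierarchy involving '%s'.", cl$name[i]),
          "provdash_validation_error"
        )
      }
      seen <- c(seen, k)
      k <- unname(parent_of[[k]])
    }
    core[i] <- roots[label_key(roots) == k]
  }
  cl$prov_core <- core

  inst <- o$instances
  unknown <- !(label_key(inst$class) %in% key)
  if (any(unknown)) {
    abort_provdash(
      sprintf(
        "Instance(s) with undeclared owning class: %s",
        paste(sprintf("'%s' (class '%s')", inst$label[unknown], inst$class[unknown]), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }
  # canonicalize owning-class spelling to the declared form
  inst$class <- cl$name[match(label_key(inst$class), key)]
  ikey <- paste(label_key(inst$class), label_key(inst$label), sep = "\r")
  if (anyDuplicated(ikey)) {
    d <- inst[duplicated(ikey), ]
    abort_provdash(
      sprintf(
        "Duplicate instance(s) under case-insensitive comparison: %s",
        paste(sprintf("'%s' in '%s'", d$label, d$class), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }

  rel <- o$relations
  if (nrow(rel) > 0L) {
    bad_pred <- !(rel$predicate %in% prov_predicates())
    if (any(bad_pred)) {
      abort_provdash(
        sprintf(
          "Relation predicate(s) outside the controlled vocabulary {%s}: %s",
          paste(prov_predicates(), collapse = ", "),
          paste(unique(rel$predicate[bad_pred]), collapse = ", ")
        ),
        "provdash_vocabulary_error"
      )
    }
    resolve <- function(class, label) {
      match(paste(label_key(class), label_key(label), sep = "\r"), ikey)
    }
    si <- resolve(rel$subject_class, rel$subject)
    oi <- resolve(rel$object_class, rel$object)
    bad <- is.na(si) | is.na(oi)
    if (any(bad)) {
      b <- rel[bad, ]
      abort_provdash(
        sprintf(
          "Relation(s) referencing undeclared instances: %s",
          paste(sprintf("(%s:%s %s %s:%s)", b$subject_class, b$subject,
                        b$predicate, b$object_class, b$object), collapse = "; ")
        ),
        "provdash_validation_error"
      )
    }
    # canonicalize to declared spellings
    rel$subject_class <- inst$class[si]; rel$subject <- inst$label[si]
    rel$object_class <- inst$class[oi]; rel$object <- inst$label[oi]
  }

  o$classes <- cl[order(label_key(cl$name), method = "radix"), ]
  o$instances <- inst[order(label_key(inst$class), label_key(inst$label), method = "radix"), ]
  o$relations <- rel[order(label_key(rel$subject_class), label_key(rel$subject),
                           rel$predicate, label_key(rel$object_class),
                           label_key(rel$object), method = "radix"), ]
  o
}

#' @export
print.provdash_ontology <- function(x, ...) {
  cat(sprintf(
    "<provdash_ontology> %d classes, %d instances, %d relations\n",
    nrow(x$classes), nrow(x$instances), nrow(x$relations)
  ))
  invisible(x)
}

# Resolve a class name case-insensitively to its canonical declared form.
resolve_class <- function(o, class_name) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  i <- match(label_key(class_name), label_key(o$classes$name))
  if (is.na(i)) {
    near <- nearest_matches(class_name, o$classes$name)
    abort_provdash(
      sprintf(
        "Unknown ontology class '%s'. Did you mean: %s?",
        class_name, paste(near, collapse = ", ")
      ),
      "provdash_lookup_error"
    )
  }
  o$classes$name[i]
}

# Canonical names of `class_name` and all of its descendants.
class_descendants <- function(o, class_name) {
  start <- resolve_class(o, class_name)
  out <- start
  frontier <- start
  while (length(frontier) > 0L) {
    kids <- o$classes$name[!is.na(o$classes$parent) &
                             label_key(o$classes$parent) %in% label_key(frontier)]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Instance values of an ontology class
#'
#' Returns the instance values owned by `class_name` or any of its
#' descendant classes, in case-folded lexicographic order. This is the set a
#' query builder offers in the drop-down for the class before any filtering.
#'
#' @param o A [ontology()] object.
#' @param class_name Class name; matched case-insensitively after whitespace
#'   normalization. Unknown names raise a lookup error that suggests the
#'   nearest declared class names.
#' @return A tibble with columns `class` (owning class) and `label`.
#' @export
instances_of <- function(o, class_name) {
  stopifnot(inherits(o, "provdash_ontology"))
  keep <- class_descendants(o, class_name)
  out <- o$instances[label_key(o$instances$class) %in% label_key(keep), ]
  out[order(label_key(out$label), method = "radix"), ]
}

# Resolve an instance label to its (class, label) canonical pair.
resolve_instance <- function(o, label, class_name = NULL) {
  inst <- o$instances
  hit <- label_key(inst$label) == label_key(label)
  if (!is.null(class_name)) {
    hit <- hit & label_key(inst$class) %in% label_key(class_descendants(o, class_name))
  }
  idx <- which(hit)
  if (length(idx) == 0L) {
    near <- nearest_matches(label, inst$label)
    abort_provdash(
      sprintf("Unknown instance '%s'. Did you mean: %s?", label,
              paste(unique(near), collapse = ", ")),
      "provdash_lookup_error"
    )
  }
  if (length(idx) > 1L) {
    abort_provdash(
      sprintf(
        "Instance label '%s' is ambiguous across classes (%s); supply `class_name`.",
        label, paste(inst$class[idx], collapse = ", ")
      ),
      "provdash_lookup_error"
    )
  }
  inst[idx, ]
}

#' Instances related to a given instance
#'
#' Looks up the instance-level relation assertions of `instance` under
#' `predicate` and returns the related instances owned by `target_class`
#' (or its descendants). The lookup is symmetric: assertions in which the
#' instance appears as subject or as object both count, so the constraint
#' "EPHB2 hadRole HCT116" answers both "which cell lines go with EPHB2?" and
#' "which bait genes go with HCT116?".
#'
#' @inheritParams instances_of
#' @param instance Instance label (case-insensitive). If the label occurs in
#'   more than one class, disambiguate with `instance_class`.
#' @param predicate One of [prov_predicates()], or `NULL` to pool all
#'   predicates.
#' @param target_class Class owning the returned instances.
#' @param instance_class Optional owning class of `instance`.
#' @return A tibble with columns `class` and `label`, sorted case-folded.
#' @export
related_instances <- function(o, instance, predicate, target_class,
                              instance_class = NULL) {
  stopifnot(inherits(o, "provdash_ontology"))
  if (!is.null(predicate) && !(predicate %in% prov_predicates())) {
    abort_provdash(
      sprintf(
        "Unknown predicate '%s'; the controlled vocabulary is {%s}.",
        predicate, paste(prov_predicates(), collapse = ", ")
      ),
      "provdash_vocabulary_error"
    )
  }
  inst <- resolve_instance(o, instance, instance_class)
  targets <- label_key(class_descendants(o, target_class))
  rel <- o$relations
  if (!is.null(predicate)) rel <- rel[rel$predicate == predicate, ]

  fwd <- rel[label_key(rel$subject) == label_key(inst$label) &
               label_key(rel$subject_class) == label_key(inst$class) &
               label_key(rel$object_class) %in% targets, c("object_class", "object")]
  bwd <- rel[label_key(rel$object) == label_key(inst$label) &
               label_key(rel$object_class) == label_key(inst$class) &
               label_key(rel$subject_class) %in% targets, c("subject_class", "subject")]
  out <- dplyr::bind_rows(
    stats::setNames(fwd, c("class", "label")),
    stats::setNames(bwd, c("class", "label"))
  )
  out <- dplyr::distinct(out)
  out[order(label_key(out$label), method = "radix"), ]
}

# TRUE if `instance` participates in any relation assertion whose other end
# is owned by `other_class` (used to decide whether the ontology constrains
# a facet at all).
has_relations_to <- function(o, instance_class, instance, other_class) {
  targets <- label_key(class_descendants(o, other_class))
  rel <- o$relations
  any(label_key(rel$subject) == label_key(instance) &
        label_key(rel$subject_class) == label_key(instance_class) &
        label_key(rel$object_class) %in% targets) ||
    any(label_key(rel$object) == label_key(instance) &
          label_key(rel$object_class) == label_key(instance_class) &
          label_key(rel$subject_class) %in% targets)
}

#' @export
tidy.provdash_ontology <- function(x, ...) {
  dplyr::left_join(
    x$instances,
    x$classes[, c("name", "parent", "prov_core")],
    by = c(class = "name")
  )
}

#' @export
glance.provdash_ontology <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_instances = nrow(x$instances),
    n_relations = nrow(x$relations)
  )
}
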