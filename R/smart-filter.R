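# Smart filtering: restrict the facet values offered to the user to those
# guaranteed to return non-empty results, combining (by intersection) data
# co-occurrence under the already-selected conditions with the ontology's
# instance-level relations.

#' Candidate facet values given a partial query pattern
#'
#' For each mapped class `C`, the candidate set is the intersection of two
#' filters:
#'
#' * data co-occurrence: values of `C` occurring in at least one experiment
#'   satisfying the *conjunction* of all currently selected conditions
#'   (existing conditions on `C` itself are excluded, the usual
#'   faceted-search self-exclusion, so the current value stays selectable);
#' * ontology admissibility: for every selected value that carries relation
#'   assertions toward `C`, only the related instances survive. Selected
#'   values without assertions toward `C` place no restriction.
#'
#' The conjunctive reading of the selected conditions is deliberate
#' regardless of the pattern's connectives: under OR no choice could ever
#' empty the result, so only the conjunction gives the filter its pruning
#' power. Every offered value therefore yields at least one match when
#' appended with AND.
#'
#' @param p_partial A [query_pattern()]; conditions with `NA` values are
#'   treated as pending and ignored.
#' @param editing_class Class being edited, or `NULL` for candidates for
#'   every mapped class.
#' @param s A `provdash_store`.
#' @param o A [ontology()] object.
#' @return A `provdash_candidates` object: named list mapping class name to
#'   a case-folded-sorted character vector of admissible values. Empty
#'   vectors are valid output.
#' @export
smart_filter <- function(p_partial, editing_class = NULL, s, o) {
  stopifnot(inherits(p_partial, "provdash_pattern"),
            inherits(s, "provdash_store"),
            inherits(o, "provdash_ontology"))
  cfg <- store_config(s)
  classes <- if (is.null(editing_class)) {
    cfg$mappings$class
  } else {
    i <- match(label_key(editing_class), label_key(cfg$mappings$class))
    if (is.na(i)) {
      near <- nearest_matches(editing_class, cfg$mappings$class)
      abort_provdash(
        sprintf("Class '%s' is not a mapped facet. Did you mean: %s?",
                editing_class, paste(near, collapse = ", ")),
        "provdash_lookup_error"
      )
    }
    cfg$mappings$class[i]
  }
  selected <- p_partial$conditions[!is.na(p_partial$conditions$value), , drop = FALSE]

  out <- lapply(classes, function(cls) {
    col <- mapped_column(cfg, cls)
    context <- selected[label_key(selected$class) != label_key(cls), , drop = FALSE]
    keep <- rep(TRUE, nrow(s$experiments))
    for (i in seq_len(nrow(context))) {
      keep <- keep & condition_matches(s, context$class[i], context$value[i])
    }
    values <- s$experiments[[col]][keep]
    values <- values[!duplicated(label_key(values))]

    # ontology admissibility under the selected instance-level relations
    for (i in seq_len(nrow(context))) {
      v <- context$value[i]
      v_class <- context$class[i]
      known <- tryCatch(
        { resolve_instance(o, v, v_class); TRUE },
        provdash_lookup_error = function(e) FALSE
      )
      if (!known) next  # values outside the ontology are unconstrained
      if (!has_relations_to(o, v_class, v, cls)) next
      allowed <- related_instances(o, v, NULL, cls, instance_class = v_class)$label
      values <- values[label_key(values) %in% label_key(allowed)]
    }
    cfold_sort(values)
  })
  names(out) <- classes
  structure(out, class = "provdash_candidates")
}

#' @export
print.provdash_candidates <- function(x, ...) {
  cat("<provdash_candidates>\n")
  for (cls in names(x)) {
    cat(sprintf("  %s: %s\n", cls,
                if (length(x[[cls]]) == 0L) "(none)" else paste(x[[cls]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.provdash_candidates <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(values, class) {
    tibble::tibble(class = class, value = values)
  })
}

#' Propagate an edited condition value through a pattern
#'
#' After the user changes the value of one condition, every other condition
#' whose current value has become incompatible with the changed value's
#' instance-level relations is repaired: if the related-instance set for
#' that condition's class is a singleton, the value is replaced by it
#' (e.g. switching the bait gene from CTNNB1 to EPHB2 rewrites the cell
#' line to HCT116); if the set has several members or is empty, the value
#' is cleared (`NA`) and the condition slot is left pending rather than
#' guessing. Conditions whose class has no relation assertions from the
#' changed value, and conditions whose value is still compatible, are left
#' untouched.
#'
#' @param p A [query_pattern()].
#' @param changed_index Position (1-based) of the condition that was just
#'   edited.
#' @param o A [ontology()] object.
#' @return The repaired `provdash_pattern`.
#' @export
propagate <- function(p, changed_index, o) {
  stopifnot(inherits(p, "provdash_pattern"), inherits(o, "provdash_ontology"))
  n <- nrow(p$conditions)
  if (!is_count(changed_index) || changed_index > n) {
    abort_provdash(
      sprintf("`changed_index` must name one of the %d condition(s).", n),
      "provdash_lookup_error"
    )
  }
  changed <- p$conditions[changed_index, ]
  if (is.na(changed$value)) return(p)
  known <- tryCatch(
    { resolve_instance(o, changed$value, changed$class); TRUE },
    provdash_lookup_error = function(e) FALSE
  )
  if (!known) return(p)

  for (i in setdiff(seq_len(n), changed_index)) {
    cls <- p$conditions$class[i]
    if (label_key(cls) == label_key(changed$class)) next
    if (!has_relations_to(o, changed$class, changed$value, cls)) next
    allowed <- related_instances(o, changed$value, NULL, cls,
                                 instance_class = changed$class)$label
    current <- p$conditions$value[i]
    if (!is.na(current) && label_key(current) %in% label_key(allowed)) next
    p$conditions$value[i] <- if (length(allowed) == 1L) allowed else NA_character_
  }
  p
}
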