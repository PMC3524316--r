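# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's evaluation code paths: they re-derive matching by direct
# per-record scans over the raw experiment table.

.fixture_cache <- new.env(parent = emptyenv())

# Default 1,000-record / 7-project store (seed 42), generated once per run.
default_store <- function() {
  if (is.null(.fixture_cache$store)) {
    .fixture_cache$store <- generate_store(generator_spec(), builtin_ontology())
  }
  .fixture_cache$store
}

oracle_norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

# Column of the store holding a facet, resolved independently of the
# package's mapped_column().
oracle_column <- function(s, class_name) {
  i <- match(oracle_norm(class_name), oracle_norm(s$mapping$class))
  stopifnot(!is.na(i))
  s$mapping$column[i]
}

# Per-record left-to-right boolean fold oracle: returns the logical match
# vector for a pattern, computed row by row.
fold_oracle <- function(p, s) {
  conds <- p$conditions
  conns <- p$connectives
  n <- nrow(s$experiments)
  if (nrow(conds) == 0L) return(rep(TRUE, n))
  cols <- vapply(conds$class, function(cl) oracle_column(s, cl), "")
  vals <- oracle_norm(conds$value)
  colcache <- lapply(cols, function(cl) oracle_norm(s$experiments[[cl]]))
  vapply(seq_len(n), function(r) {
    acc <- colcache[[1]][r] == vals[1]
    for (i in seq_len(nrow(conds))[-1]) {
      t <- colcache[[i]][r] == vals[i]
      acc <- if (conns[i - 1L] == "AND") acc && t else acc || t
    }
    acc
  }, TRUE)
}

# Linear-scan count of records matching a conjunction of (class, value)
# pairs, independent of evaluate()/smart_filter().
scan_count <- function(s, classes, values) {
  keep <- rep(TRUE, nrow(s$experiments))
  for (i in seq_along(classes)) {
    col <- oracle_column(s, classes[i])
    keep <- keep & (oracle_norm(s$experiments[[col]]) == oracle_norm(values[i]))
  }
  sum(keep)
}

sorted_match_ids <- function(res) sort(tidy(res)$experiment_id)

# Random valid pattern over the mapped facets of a store (uses the caller's
# RNG stream; seed it before use).
random_pattern <- function(s, o, n_conditions) {
  classes <- s$mapping$class
  picks <- sample(classes, n_conditions, replace = TRUE)
  values <- vapply(picks, function(cl) {
    labs <- instances_of(o, cl)$label
    sample(labs, 1L)
  }, "")
  query_pattern(
    tibble::tibble(class = picks, value = unname(values)),
    if (n_conditions > 1L) sample(c("AND", "OR"), n_conditions - 1L, replace = TRUE) else character()
  )
}

# Random valid ontology: a random class tree under the three PROV-O roots,
# random instances, random well-formed relation assertions.
random_ontology <- function(max_classes = 6L) {
  n_cls <- sample(2:max_classes, 1L)
  names <- sprintf("Class %02d %s", seq_len(n_cls),
                   replicate(n_cls, paste(sample(letters, 4L), collapse = "")))
  parents <- character(n_cls)
  for (i in seq_len(n_cls)) {
    pool <- c(prov_roots(), names[seq_len(i - 1L)])
    parents[i] <- sample(pool, 1L)
  }
  classes <- tibble::tibble(name = names, parent = parents)
  inst <- do.call(rbind, lapply(seq_len(n_cls), function(i) {
    k <- sample(0:4, 1L)
    if (k == 0L) return(NULL)
    data.frame(class = names[i],
               label = sprintf("val %d %s", seq_len(k),
                               replicate(k, paste(sample(letters, 5L), collapse = ""))))
  }))
  if (is.null(inst)) inst <- data.frame(class = character(), label = character())
  relations <- NULL
  if (nrow(inst) >= 2L) {
    n_rel <- sample(0:min(4L, nrow(inst)), 1L)
    if (n_rel > 0L) {
      si <- sample(nrow(inst), n_rel, replace = TRUE)
      oi <- sample(nrow(inst), n_rel, replace = TRUE)
      relations <- tibble::tibble(
        subject_class = inst$class[si], subject = inst$label[si],
        predicate = sample(prov_predicates(), n_rel, replace = TRUE),
        object_class = inst$class[oi], object = inst$label[oi]
      )
      relations <- unique(relations)
    }
  }
  ontology(classes, inst, relations)
}

ontology_equal <- function(a, b) {
  identical(a$classes, b$classes) &&
    identical(a$instances, b$instances) &&
    identical(a$relations, b$relations)
}

# Ontology variant in which one bait gene is compatible with two cell
# lines, used to check that propagation clears rather than guesses.
multi_compatible_ontology <- function() {
  o <- builtin_ontology()
  extra <- tibble::tibble(
    subject_class = "Bait gene", subject = "EPHB2", predicate = "hadRole",
    object_class = "Cell line", object = "RKO"
  )
  ontology(o$classes[, c("name", "parent")], o$instances,
           rbind(o$relations, extra))
}
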