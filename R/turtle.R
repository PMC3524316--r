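# Turtle (RDF) serialization of the ontology.
#
# The on-disk form is standard Turtle restricted to the constructs the
# ontology model needs: prefixed names, rdfs:Class declarations with
# rdfs:subClassOf chains, instance typing via rdf:type, rdfs:label literals,
# and instance-level triples with prov: predicates. Core classes live in the
# W3C PROV namespace; domain classes and instances in a project namespace.

TTL_PREFIXES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  prov = "http://www.w3.org/ns/prov#",
  pv   = "http://provdash.org/ns#"
)

# Local-name sanitizer: Turtle PN_LOCAL-safe, deterministic.
ttl_local <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", norm_ws(x))
  x <- gsub("^_+|_+$", "", x)
  ifelse(grepl("^[A-Za-z]", x), x, paste0("x", x))
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

class_iri <- function(name) {
  if (name %in% prov_roots()) paste0("prov:", name) else paste0("pv:", ttl_local(name))
}

instance_iri <- function(class, label) {
  paste0("pv:", ttl_local(class), "_", ttl_local(label))
}

#' Write an ontology to a Turtle file
#'
#' Serializes the ontology to Turtle. [load_ontology()] of the written file
#' reconstructs a structurally identical ontology (canonical label spellings,
#' hierarchy, instances and relation assertions all survive the round trip).
#'
#' @param o A [ontology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ontology <- function(o, path) {
  stopifnot(inherits(o, "provdash_ontology"))
  lines <- c(
    sprintf("@prefix %s: <%s> .", names(TTL_PREFIXES), unname(TTL_PREFIXES)),
    ""
  )
  for (i in seq_len(nrow(o$classes))) {
    name <- o$classes$name[i]
    parent <- o$classes$parent[i]
    body <- sprintf('%s a rdfs:Class ;\n    rdfs:label "%s"', class_iri(name), ttl_escape(name))
    if (!is.na(parent)) {
      body <- paste0(body, sprintf(" ;\n    rdfs:subClassOf %s", class_iri(parent)))
    }
    lines <- c(lines, paste0(body, " ."), "")
  }
  for (i in seq_len(nrow(o$instances))) {
    cls <- o$instances$class[i]
    lab <- o$instances$label[i]
    lines <- c(lines, sprintf(
      '%s a %s ;\n    rdfs:label "%s" .',
      instance_iri(cls, lab), class_iri(cls), ttl_escape(lab)
    ), "")
  }
  r <- o$relations
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%s prov:%s %s .",
      instance_iri(r$subject_class[i], r$subject[i]),
      r$predicate[i],
      instance_iri(r$object_class[i], r$object[i])
    ))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# --- Turtle tokenizer -------------------------------------------------------

# Token types: iri ("<...>"), pname ("pfx:local"), string literal, keyword
# ("a", "@prefix"), punctuation (";", ",", "."). Line numbers are kept for
# error messages.
ttl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tokens <- list()
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
      if (ch == "#") break  # comment to end of line
      if (ch == '"') {
        j <- i + 1L
        val <- character()
        closed <- FALSE
        while (j <= n) {
          cj <- substr(s, j, j)
          if (cj == "\\") {
            nxt <- substr(s, j + 1L, j + 1L)
            val <- c(val, if (nxt == '"') '"' else if (nxt == "\\") "\\" else nxt)
            j <- j + 2L
          } else if (cj == '"') {
            closed <- TRUE
            break
          } else {
            val <- c(val, cj)
            j <- j + 1L
          }
        }
        if (!closed) {
          abort_provdash(
            sprintf("Turtle parse error at line %d: unterminated string literal.", ln),
            "provdash_format_error"
          )
        }
        tokens[[length(tokens) + 1L]] <- list(type = "string", value = paste(val, collapse = ""), line = ln)
        i <- j + 1L
        next
      }
      if (ch == "<") {
        j <- regexpr(">", substr(s, i, n), fixed = TRUE)
        if (j == -1L) {
          abort_provdash(
            sprintf("Turtle parse error at line %d: unterminated IRI.", ln),
            "provdash_format_error"
          )
        }
        tokens[[length(tokens) + 1L]] <- list(
          type = "iri", value = substr(s, i + 1L, i + j - 2L), line = ln
        )
        i <- i + j
        next
      }
      if (ch %in% c(";", ",", ".")) {
        tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, line = ln)
        i <- i + 1L
        next
      }
      m <- regexpr("^[^[:space:];,\"<>#]+", substr(s, i, n))
      word <- regmatches(substr(s, i, n), m)
      # a bare word may end with the statement terminator "."
      trailing_dot <- grepl("\\.$", word) && !grepl(":", word)
      if (trailing_dot) word <- sub("\\.$", "", word)
      if (nchar(word) > 0L) {
        type <- if (word %in% c("a", "@prefix")) "keyword" else "pname"
        tokens[[length(tokens) + 1L]] <- list(type = type, value = word, line = ln)
      }
      if (trailing_dot) tokens[[length(tokens) + 1L]] <- list(type = ".", value = ".", line = ln)
      i <- i + attr(m, "match.length")
      next
    }
  }
  tokens
}

# Parse token stream into triples (subject, predicate, object, object_type).
ttl_triples <- function(tokens) {
  triples <- list()
  prefixes <- character()
  i <- 1L
  n <- length(tokens)
  tk <- function(j) if (j <= n) tokens[[j]] else NULL

  expand <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "keyword" && tok$value == "a") {
      return(paste0(TTL_PREFIXES[["rdf"]], "type"))
    }
    parts <- strsplit(tok$value, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !(parts[1] %in% names(prefixes))) {
      abort_provdash(
        sprintf("Turtle parse error at line %d: unknown prefix in '%s'.", tok$line, tok$value),
        "provdash_format_error"
      )
    }
    paste0(prefixes[[parts[1]]], parts[2])
  }

  while (i <= n) {
    t <- tk(i)
    if (t$type == "keyword" && t$value == "@prefix") {
      pfx <- tk(i + 1L); iri <- tk(i + 2L); dot <- tk(i + 3L)
      if (is.null(dot) || pfx$type != "pname" || iri$type != "iri" || dot$type != ".") {
        abort_provdash(
          sprintf("Turtle parse error at line %d: malformed @prefix directive.", t$line),
          "provdash_format_error"
        )
      }
      prefixes[[sub(":$", "", pfx$value)]] <- iri$value
      i <- i + 4L
      next
    }
    if (!(t$type %in% c("pname", "iri"))) {
      abort_provdash(
        sprintf("Turtle parse error at line %d: expected a subject, got '%s'.", t$line, t$value),
        "provdash_format_error"
      )
    }
    subj <- expand(t)
    i <- i + 1L
    repeat {
      pt <- tk(i)
      if (is.null(pt) || !(pt$type %in% c("pname", "iri", "keyword"))) {
        abort_provdash(
          sprintf("Turtle parse error at line %d: expected a predicate.", (pt %||% t)$line),
          "provdash_format_error"
        )
      }
      pred <- expand(pt)
      ot <- tk(i + 1L)
      if (is.null(ot) || !(ot$type %in% c("pname", "iri", "string"))) {
        abort_provdash(
          sprintf("Turtle parse error at line %d: expected an object.", pt$line),
          "provdash_format_error"
        )
      }
      obj <- if (ot$type == "string") ot$value else expand(ot)
      triples[[length(triples) + 1L]] <- list(
        subject = subj, predicate = pred,
        object = obj, object_is_literal = (ot$type == "string"), line = ot$line
      )
      sep <- tk(i + 2L)
      if (is.null(sep) || !(sep$type %in% c(";", "."))) {
        abort_provdash(
          sprintf("Turtle parse error at line %d: statement must continue with ';' or end with '.'.", ot$line),
          "provdash_format_error"
        )
      }
      i <- i + 3L
      if (sep$type == ".") break
    }
  }
  triples
}

#' Load an ontology from a Turtle file
#'
#' Reads the Turtle serialization written by [save_ontology()] (standard
#' Turtle: `@prefix` directives, `rdfs:Class` declarations with
#' `rdfs:subClassOf` and `rdfs:label`, `rdf:type` instance declarations, and
#' instance-level triples with `prov:` predicates) and validates the result.
#' Syntax problems raise a format error naming the offending line; semantic
#' problems (undeclared classes, duplicate labels, cyclic hierarchies,
#' multiple inheritance, unresolvable relation ends) raise a validation
#' error listing the offending declarations.
#'
#' @param path Path to a Turtle file.
#' @return A validated [ontology()] object.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) {
    abort_provdash(sprintf("Ontology file not found: %s", path), "provdash_io_error")
  }
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  triples <- ttl_triples(ttl_tokenize(text))

  rdf_type <- paste0(TTL_PREFIXES[["rdf"]], "type")
  rdfs_class <- paste0(TTL_PREFIXES[["rdfs"]], "Class")
  rdfs_label <- paste0(TTL_PREFIXES[["rdfs"]], "label")
  rdfs_subclass <- paste0(TTL_PREFIXES[["rdfs"]], "subClassOf")
  prov_ns <- TTL_PREFIXES[["prov"]]

  subj_of <- vapply(triples, `[[`, "", "subject")
  pred_of <- vapply(triples, `[[`, "", "predicate")
  obj_of <- vapply(triples, `[[`, "", "object")

  prov_root_iri <- paste0(prov_ns, prov_roots())
  class_iris <- unique(c(
    subj_of[pred_of == rdf_type & obj_of == rdfs_class],
    intersect(subj_of, prov_root_iri)
  ))

  labels <- stats::setNames(rep(NA_character_, length(unique(subj_of))), unique(subj_of))
  for (tr in triples) {
    if (tr$predicate == rdfs_label) {
      if (!tr$object_is_literal) {
        abort_provdash(
          sprintf("Turtle parse error at line %d: rdfs:label must be a string literal.", tr$line),
          "provdash_format_error"
        )
      }
      labels[[tr$subject]] <- tr$object
    }
  }
  iri_label <- function(iri) {
    lb <- labels[[iri]]
    if (!is.na(lb)) return(lb)
    if (iri %in% prov_root_iri) return(prov_roots()[prov_root_iri == iri])
    gsub("_", " ", sub("^.*[#/]", "", iri))
  }

  # classes + single-parent check
  parents <- list()
  for (tr in triples[pred_of == rdfs_subclass]) {
    parents[[tr$subject]] <- c(parents[[tr$subject]], tr$object)
  }
  multi <- names(parents)[vapply(parents, function(p) length(unique(p)) > 1L, TRUE)]
  if (length(multi) > 0L) {
    abort_provdash(
      sprintf(
        "Multiple inheritance is not supported; offending class(es): %s",
        paste(vapply(multi, iri_label, ""), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }
  class_iris <- unique(c(class_iris, prov_root_iri[prov_root_iri %in% unlist(parents)]))
  classes <- tibble::tibble(
    iri = class_iris,
    name = vapply(class_iris, iri_label, ""),
    parent_iri = vapply(class_iris, function(ci) {
      p <- parents[[ci]]
      if (is.null(p)) NA_character_ else unique(p)[1]
    }, "")
  )
  undeclared_parent <- !is.na(classes$parent_iri) & !(classes$parent_iri %in% class_iris)
  if (any(undeclared_parent)) {
    abort_provdash(
      sprintf(
        "Parent class(es) not declared: %s",
        paste(unique(classes$parent_iri[undeclared_parent]), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }
  classes$parent <- ifelse(
    is.na(classes$parent_iri), NA_character_,
    classes$name[match(classes$parent_iri, classes$iri)]
  )

  # instances: rdf:type to a declared non-rdfs:Class type
  inst_rows <- triples[pred_of == rdf_type & obj_of != rdfs_class]
  instances <- tibble::tibble(
    iri = vapply(inst_rows, `[[`, "", "subject"),
    class_iri = vapply(inst_rows, `[[`, "", "object"),
    line = vapply(inst_rows, `[[`, 1L, "line")
  )
  instances <- instances[!(instances$iri %in% class_iris), ]
  unknown_cls <- !(instances$class_iri %in% class_iris)
  if (any(unknown_cls)) {
    b <- instances[unknown_cls, ]
    abort_provdash(
      sprintf(
        "Instance(s) typed with undeclared class: %s",
        paste(sprintf("<%s> (line %d)", b$iri, b$line), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }
  multi_type <- instances$iri[duplicated(instances$iri)]
  if (length(multi_type) > 0L) {
    abort_provdash(
      sprintf(
        "Instance(s) typed with more than one class: %s",
        paste(unique(vapply(multi_type, iri_label, "")), collapse = ", ")
      ),
      "provdash_validation_error"
    )
  }
  instances$class <- classes$name[match(instances$class_iri, classes$iri)]
  instances$label <- vapply(instances$iri, iri_label, "")

  # instance-level relations with prov predicates
  is_rel <- startsWith(pred_of, prov_ns) & pred_of != rdf_type
  rel_rows <- triples[is_rel]
  rel <- empty_relations()
  if (length(rel_rows) > 0L) {
    rsubj <- vapply(rel_rows, `[[`, "", "subject")
    robj <- vapply(rel_rows, `[[`, "", "object")
    rpred <- sub(prov_ns, "", vapply(rel_rows, `[[`, "", "predicate"), fixed = TRUE)
    si <- match(rsubj, instances$iri)
    oi <- match(robj, instances$iri)
    if (anyNA(si) || anyNA(oi)) {
      bad <- which(is.na(si) | is.na(oi))[1]
      abort_provdash(
        sprintf(
          "Relation at line %d references an undeclared instance: <%s> prov:%s <%s>.",
          rel_rows[[bad]]$line, rsubj[bad], rpred[bad], robj[bad]
        ),
        "provdash_validation_error"
      )
    }
    rel <- tibble::tibble(
      subject_class = instances$class[si], subject = instances$label[si],
      predicate = rpred,
      object_class = instances$class[oi], object = instances$label[oi]
    )
  }

  ontology(
    classes = classes[, c("name", "parent")],
    instances = instances[, c("class", "label")],
    relations = rel
  )
}
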