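test_that("packaged ontology exposes the expected facet vocabularies", {
  o <- load_ontology(builtin_ontology_path())
  expect_setequal(
    instances_of(o, "Bait Type")$label,
    c("Endogenous", "Exogenous", "KnockIn", "Tagged", "Untagged")
  )
  expect_true(all(c("Embryonic stem", "Epilast stem cell", "HCT116") %in%
                    instances_of(o, "Cell line")$label))
  expect_true(all(c("Bait Type", "Cell line", "Bait gene") %in% o$classes$name))
  # class lookup is case-insensitive and descendant-inclusive
  expect_identical(instances_of(o, "cell LINE"), instances_of(o, "Cell line"))
  expect_true(nrow(instances_of(o, "Sample")) >= nrow(instances_of(o, "Cell line")))
})

test_that("an ontology with only the PROV-O roots is valid and empty", {
  o <- ontology()
  expect_setequal(o$classes$name, c("Activity", "Entity", "Agent"))
  expect_identical(nrow(o$instances), 0L)
  expect_identical(o$classes$prov_core, sort(prov_roots()))
  f <- tempfile(fileext = ".ttl")
  save_ontology(o, f)
  expect_true(ontology_equal(o, load_ontology(f)))
})

test_that("validation rejects malformed ontologies", {
  expect_error(
    ontology(instances = data.frame(class = "Instrument", label = "LTQ")),
    class = "provdash_validation_error"
  )
  expect_error(
    ontology(classes = data.frame(name = c("A1", "a1"), parent = "Entity")),
    class = "provdash_validation_error"
  )
  expect_error(
    ontology(
      classes = data.frame(name = "Bait Type", parent = "Entity"),
      instances = data.frame(class = "Bait Type", label = c("Tagged", "TAGGED"))
    ),
    class = "provdash_validation_error"
  )
  expect_error(
    ontology(classes = data.frame(name = c("A", "B"), parent = c("B", "A"))),
    class = "provdash_validation_error"
  )
  expect_error(
    ontology(
      classes = data.frame(name = "C", parent = "Entity"),
      instances = data.frame(class = "C", label = c("x", "y")),
      relations = data.frame(subject_class = "C", subject = "x",
                             predicate = "linkedTo", object_class = "C", object = "y")
    ),
    class = "provdash_vocabulary_error"
  )
  expect_error(
    ontology(
      classes = data.frame(name = "C", parent = "Entity"),
      instances = data.frame(class = "C", label = "x"),
      relations = data.frame(subject_class = "C", subject = "x",
                             predicate = "hadRole", object_class = "C", object = "ghost")
    ),
    class = "provdash_validation_error"
  )
})

test_that("turtle loader reports syntax and semantic problems precisely", {
  f <- tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix pv: <http://provdash.org/ns#> .",
    "pv:Thing a pv:UndeclaredClass ."
  ), f)
  expect_error(load_ontology(f), class = "provdash_validation_error")

  writeLines('pv:Broken a "unclosed', f)
  expect_error(load_ontology(f), "line 1", class = "provdash_format_error")

  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix prov: <http://www.w3.org/ns/prov#> .",
    "@prefix pv: <http://provdash.org/ns#> .",
    "pv:C a rdfs:Class ; rdfs:subClassOf prov:Entity ; rdfs:subClassOf prov:Activity ."
  ), f)
  expect_error(load_ontology(f), "inheritance", class = "provdash_validation_error")

  expect_error(load_ontology(tempfile()), class = "provdash_io_error")
})

test_that("related_instances honors the EPHB2/HCT116 linkage and symmetry", {
  o <- builtin_ontology()
  expect_identical(
    related_instances(o, "EPHB2", "hadRole", "Cell line")$label,
    "HCT116"
  )
  expect_identical(related_instances(o, "HCT116", "hadRole", "Bait gene")$label, "EPHB2")
  expect_identical(nrow(related_instances(o, "DNMT1", "hadRole", "Cell line")), 0L)
  expect_error(related_instances(o, "EPHB2", "causedBy", "Cell line"),
               class = "provdash_vocabulary_error")
  expect_error(instances_of(o, "Bait"), "Did you mean", class = "provdash_lookup_error")
})

test_that("related_instances agrees with a brute-force relation scan", {
  o <- builtin_ontology()
  rel <- o$relations
  for (lab in c("CTNNB1", "POU5F1", "APC", "HCT116")) {
    for (target in c("Cell line", "Bait gene")) {
      got <- related_instances(o, lab, "hadRole", target)$label
      manual <- character()
      for (i in seq_len(nrow(rel))) {
        if (rel$predicate[i] != "hadRole") next
        if (tolower(rel$subject[i]) == tolower(lab) && rel$object_class[i] == target) {
          manual <- c(manual, rel$object[i])
        }
        if (tolower(rel$object[i]) == tolower(lab) && rel$subject_class[i] == target) {
          manual <- c(manual, rel$subject[i])
        }
      }
      expect_setequal(got, unique(manual))
    }
  }
})

test_that("relation symmetry holds across random ontologies", {
  set.seed(101)
  for (rep in 1:20) {
    o <- random_ontology()
    if (nrow(o$relations) == 0L) next
    for (i in seq_len(nrow(o$relations))) {
      r <- o$relations[i, ]
      fwd <- related_instances(o, r$subject, r$predicate, r$object_class,
                               instance_class = r$subject_class)
      expect_true(r$object %in% fwd$label)
      bwd <- related_instances(o, r$object, r$predicate, r$subject_class,
                               instance_class = r$object_class)
      expect_true(r$subject %in% bwd$label)
    }
  }
})

test_that("load/save round-trips random valid ontologies", {
  set.seed(202)
  f <- tempfile(fileext = ".ttl")
  for (rep in 1:25) {
    o <- random_ontology()
    save_ontology(o, f)
    expect_true(ontology_equal(o, load_ontology(f)))
  }
})

# breadth-first descendant walk over the parent column, independent of the
# package's traversal
descendants_bfs <- function(o, root) {
  out <- root
  repeat {
    kids <- o$classes$name[!is.na(o$classes$parent) & o$classes$parent %in% out]
    new <- setdiff(kids, out)
    if (length(new) == 0L) break
    out <- c(out, new)
  }
  out
}

test_that("hierarchy traversal from the roots visits every class once", {
  set.seed(303)
  for (rep in 1:10) {
    o <- random_ontology()
    visited <- unlist(lapply(prov_roots(), function(r) descendants_bfs(o, r)))
    expect_setequal(visited, o$classes$name)
    expect_identical(anyDuplicated(visited), 0L)
  }
})

test_that("written turtle is standards-compliant (external RDF parser)", {
  f <- tempfile(fileext = ".ttl")
  save_ontology(builtin_ontology(), f)
  status <- suppressWarnings(system2(
    "python",
    c("-c", shQuote("import sys, rdflib; g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle'); print(len(g))"), f),
    stdout = TRUE, stderr = TRUE
  ))
  code <- attr(status, "status") %||% 0L
  expect_identical(code, 0L)
  expect_gt(as.integer(status[length(status)]), 50L)
})
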