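test_that("with no selections every store value is a candidate", {
  s <- default_store()
  o <- builtin_ontology()
  cand <- smart_filter(query_pattern(), NULL, s, o)
  expect_setequal(names(cand), s$mapping$class)
  for (cls in names(cand)) {
    col <- oracle_column(s, cls)
    expect_setequal(cand[[cls]], unique(s$experiments[[col]]))
  }
})

test_that("selecting EPHB2 narrows the cell line to HCT116", {
  s <- default_store()
  o <- builtin_ontology()
  p <- parse_dsl("\"Bait gene\"='EPHB2'")
  cand <- smart_filter(p, "Cell line", s, o)
  expect_identical(cand[["Cell line"]], "HCT116")
  # and symmetrically, selecting HCT116 narrows the bait gene via the ontology
  cand2 <- smart_filter(parse_dsl("\"Cell line\"='HCT116'"), "Bait gene", s, o)
  expect_identical(cand2[["Bait gene"]], "EPHB2")
})

test_that("candidates are exactly the sound and complete set", {
  s <- default_store()
  o <- builtin_ontology()
  p <- parse_dsl("Organism='Homo Sapiens'")
  cand <- smart_filter(p, "Cell line", s, o)[["Cell line"]]
  col <- oracle_column(s, "Cell line")
  all_values <- unique(s$experiments[[col]])
  for (v in all_values) {
    co_occurs <- scan_count(s, c("Organism", "Cell line"), c("Homo Sapiens", v)) > 0L
    expect_identical(v %in% cand, co_occurs, info = v)
  }
  # soundness: every offered candidate yields >= 1 match under AND-extension
  for (v in cand) {
    expect_gt(scan_count(s, c("Organism", "Cell line"), c("Homo Sapiens", v)), 0L)
  }
})

test_that("editing an existing condition excludes it from its own context", {
  s <- default_store()
  o <- builtin_ontology()
  p <- parse_dsl("\"Cell line\"='RKO' AND Organism='Homo Sapiens'")
  cand <- smart_filter(p, "Cell line", s, o)[["Cell line"]]
  # the currently selected value must remain offerable
  expect_true("RKO" %in% cand)
  expect_true(length(cand) > 1L)
})

test_that("conjunctive narrowing is monotone", {
  s <- default_store()
  o <- builtin_ontology()
  base <- smart_filter(query_pattern(), NULL, s, o)
  set.seed(606)
  for (rep in 1:15) {
    p1 <- random_pattern(s, o, 1L)
    p2 <- query_pattern(
      rbind(p1$conditions, random_pattern(s, o, 1L)$conditions),
      "AND"
    )
    c1 <- smart_filter(p1, NULL, s, o)
    c2 <- smart_filter(p2, NULL, s, o)
    for (cls in names(base)) {
      expect_true(all(c1[[cls]] %in% base[[cls]]))
      # adding a conjunct never enlarges a candidate set (self-exclusion
      # applies per class, so compare only classes outside the pattern)
      in_pattern <- tolower(cls) %in% tolower(p2$conditions$class)
      if (!in_pattern) expect_true(all(c2[[cls]] %in% c1[[cls]]))
    }
  }
})

test_that("empty candidate sets are valid output", {
  o <- builtin_ontology()
  s <- default_store()
  # a context that matches nothing: EPHB2 forces HCT116, so asking for
  # cell-line candidates under a contradictory pair yields none
  p <- parse_dsl("\"Bait gene\"='EPHB2' AND \"Cell line\"='RKO'")
  cand <- smart_filter(p, "Organism", s, o)
  expect_identical(cand[["Organism"]], character(0))
  expect_error(smart_filter(query_pattern(), "Nonexistent", s, o),
               class = "provdash_lookup_error")
})

test_that("switching the bait from CTNNB1 to EPHB2 rewrites the cell line", {
  o <- builtin_ontology()
  p <- parse_dsl("\"Bait gene\"='CTNNB1' AND \"Cell line\"='RKO'")
  p$conditions$value[1] <- "EPHB2"
  p2 <- propagate(p, 1L, o)
  expect_identical(p2$conditions$value[2], "HCT116")
  # the repaired pattern renders back to DSL
  expect_match(render_dsl(p2), "HCT116")
})

test_that("propagation leaves unrelated conditions untouched", {
  o <- builtin_ontology()
  p <- parse_dsl("\"Bait gene\"='DNMT1' AND \"Cell line\"='RKO' AND Organism='Homo Sapiens'")
  expect_identical(propagate(p, 1L, o), p)  # DNMT1 has no assertions
  p3 <- parse_dsl("\"Bait gene\"='EPHB2' AND Organism='Homo Sapiens'")
  expect_identical(propagate(p3, 1L, o), p3)  # Organism is never related
})

test_that("a multi-compatible change clears the value instead of guessing", {
  o2 <- multi_compatible_ontology()  # EPHB2 linked to both HCT116 and RKO
  p <- parse_dsl("\"Bait gene\"='CTNNB1' AND \"Cell line\"='Embryonic stem'")
  p$conditions$value[1] <- "EPHB2"
  p2 <- propagate(p, 1L, o2)
  expect_true(is.na(p2$conditions$value[2]))
  expect_identical(nrow(p2$conditions), 2L)  # slot retained, value pending
  # a compatible current value is kept
  p3 <- parse_dsl("\"Bait gene\"='CTNNB1' AND \"Cell line\"='RKO'")
  p3$conditions$value[1] <- "EPHB2"
  expect_identical(propagate(p3, 1L, o2)$conditions$value[2], "RKO")
})
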