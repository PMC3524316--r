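test_that("the empty pattern matches the whole store, grouped by project", {
  s <- default_store()
  res <- evaluate(query_pattern(), s)
  expect_identical(res$total, 1000L)
  expect_identical(sum(res$groups$n), res$total)
  expect_identical(res$groups$project_id, sort(s$projects$project_id))
  expect_identical(nrow(tidy(res)), 1000L)
  expect_identical(glance(res)$total, 1000L)
})

test_that("single-condition evaluation equals an independent linear scan", {
  s <- default_store()
  p <- parse_dsl("Organism='Homo Sapiens'")
  res <- evaluate(p, s)
  expect_identical(res$total, scan_count(s, "Organism", "Homo Sapiens"))
  expect_identical(sorted_match_ids(res),
                   sort(s$experiments$experiment_id[fold_oracle(p, s)]))
})

test_that("mixed AND/OR chains fold left to right with no precedence", {
  s <- default_store()
  # A AND B OR C must read ((A AND B) OR C), not A AND (B OR C)
  p <- parse_dsl("Organism='Mus musculus' AND \"Cell line\"='RKO' OR \"Bait gene\"='DNMT1'")
  ex <- s$experiments
  a <- tolower(ex$organism) == tolower("Mus musculus")
  b <- ex$cell_line == "RKO"
  c_ <- ex$bait_gene == "DNMT1"
  left_fold <- (a & b) | c_
  precedence <- a & (b | c_)
  expect_identical(evaluate(p, s)$total, sum(left_fold))
  expect_false(sum(left_fold) == sum(precedence))  # the two readings differ here
  for (id in c("Q3", "Q4", "Q7")) {
    q <- parse_dsl(example_queries()$dsl[example_queries()$id == id])
    expect_identical(sorted_match_ids(evaluate(q, s)),
                     sort(s$experiments$experiment_id[fold_oracle(q, s)]))
  }
})

test_that("translation parenthesizes the fold and binds every value", {
  cfg <- default_config()
  p1 <- parse_dsl("Organism='Homo Sapiens'")
  t1 <- translate(p1, cfg)
  expect_identical(t1$clause, "LOWER(organism) = LOWER(?)")
  expect_identical(t1$params, "Homo Sapiens")

  q3 <- parse_dsl(example_queries()$dsl[3])
  t3 <- translate(q3, cfg)
  expect_identical(
    t3$clause,
    paste0("(((LOWER(organism) = LOWER(?) AND LOWER(cell_line) = LOWER(?))",
           " OR LOWER(perturbation) = LOWER(?)) OR LOWER(subcellular_fraction) = LOWER(?))")
  )
  expect_identical(length(t3$params), 4L)
  # values never appear in the emitted text
  expect_false(grepl("Homo", t3$sql, fixed = TRUE))

  p_bad <- query_pattern(data.frame(class = "Instrument", value = "LTQ"))
  expect_error(translate(p_bad, cfg), "Instrument", class = "provdash_translation_error")
  expect_error(evaluate(p_bad, default_store()), "Instrument",
               class = "provdash_translation_error")
})

test_that("translated execution and in-memory evaluation agree on Q1-Q7", {
  s <- default_store()
  cfg <- default_config()
  for (dsl in example_queries()$dsl) {
    p <- parse_dsl(dsl)
    r1 <- evaluate(p, s)
    r2 <- execute_translated(translate(p, cfg), s)
    expect_identical(sorted_match_ids(r1), sorted_match_ids(r2))
    expect_identical(r1$total, r2$total)
  }
  # empty pattern through the translated route too
  expect_identical(execute_translated(translate(query_pattern(), cfg), s)$total, 1000L)
})

test_that("value matching is case-insensitive across spellings", {
  s <- default_store()
  r_upper <- evaluate(parse_dsl("Organism='Homo Sapiens'"), s)
  r_lower <- evaluate(parse_dsl("Organism='Homo sapiens'"), s)
  expect_identical(sorted_match_ids(r_upper), sorted_match_ids(r_lower))
  expect_gt(r_upper$total, 0L)
})

test_that("result grouping conserves the ungrouped match count", {
  s <- default_store()
  set.seed(505)
  for (rep in 1:25) {
    p <- random_pattern(s, builtin_ontology(), sample(1:6, 1L))
    res <- evaluate(p, s)
    expect_identical(res$total, sum(fold_oracle(p, s)))
    expect_identical(res$total, sum(res$groups$n))
    expect_identical(res$groups$project_id, sort(unique(tidy(res)$project_id)))
  }
})

test_that("link_out builds deterministic URLs", {
  e <- list(project_id = "P3", experiment_id = "E12")
  expect_identical(link_out(e, "https://labkey.example"),
                   "https://labkey.example/project/P3/experiment/E12")
  expect_identical(link_out(e, "https://labkey.example/"),
                   "https://labkey.example/project/P3/experiment/E12")
  expect_identical(link_out(e, ""), "project/P3/experiment/E12")
  expect_identical(link_out(e, "https://x"), link_out(e, "https://x"))
})

test_that("autoplot returns a per-project bar chart", {
  res <- evaluate(parse_dsl("Organism='Homo Sapiens'"), default_store())
  gg <- autoplot(res)
  expect_s3_class(gg, "ggplot")
})
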