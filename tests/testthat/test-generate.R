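test_that("generation is a pure function of spec and seed", {
  o <- builtin_ontology()
  spec <- generator_spec(n_projects = 3L, n_experiments = 120L, seed = 9L)
  s1 <- generate_store(spec, o)
  s2 <- generate_store(spec, o)
  expect_identical(s1$experiments, s2$experiments)
  expect_identical(s1$projects, s2$projects)
  s3 <- generate_store(generator_spec(n_projects = 3L, n_experiments = 120L, seed = 10L), o)
  expect_false(identical(s1$experiments, s3$experiments))
})

test_that("hard constraints hold in every generated record", {
  s <- default_store()
  o <- builtin_ontology()
  rel <- o$relations
  for (i in seq_len(nrow(rel))) {
    scol <- oracle_column(s, rel$subject_class[i])
    ocol <- oracle_column(s, rel$object_class[i])
    hit <- s$experiments[[scol]] == rel$subject[i]
    allowed <- rel$object[rel$subject == rel$subject[i] &
                            rel$subject_class == rel$subject_class[i] &
                            rel$object_class == rel$object_class[i]]
    expect_true(all(s$experiments[[ocol]][hit] %in% allowed))
  }
  # the canonical example: every EPHB2 record runs in HCT116
  ep <- s$experiments[s$experiments[[oracle_column(s, "Bait gene")]] == "EPHB2", ]
  expect_gt(nrow(ep), 0L)
  expect_true(all(ep[[oracle_column(s, "Cell line")]] == "HCT116"))
})

test_that("every vocabulary value is covered at least once", {
  s <- default_store()
  vocab <- default_vocabularies()
  for (cls in names(vocab)) {
    col <- oracle_column(s, cls)
    expect_true(all(vocab[[cls]] %in% s$experiments[[col]]),
                info = sprintf("coverage of %s", cls))
  }
})

test_that("store shape matches the spec counts and mapping", {
  s <- default_store()
  expect_identical(nrow(s$experiments), 1000L)
  expect_identical(nrow(s$projects), 7L)
  expect_identical(anyDuplicated(s$experiments$experiment_id), 0L)
  expect_true(all(s$experiments$project_id %in% s$projects$project_id))
  expect_true(all(s$projects$project_id %in% s$experiments$project_id))
  expect_setequal(
    names(s$experiments),
    c("experiment_id", "project_id", s$mapping$column, "files")
  )
  expect_true(all(lengths(s$experiments$files) == 3L))
  # linear-scan count for a single facet value matches dplyr bookkeeping
  n_human <- sum(tolower(s$experiments$organism) == tolower("Homo Sapiens"))
  expect_identical(scan_count(s, "Organism", "Homo Sapiens"), n_human)
})

test_that("unsatisfiable constraints fail with a named conflict", {
  o <- builtin_ontology()
  vocab <- default_vocabularies()
  vocab[["Cell line"]] <- setdiff(vocab[["Cell line"]], "HCT116")
  spec <- generator_spec(n_experiments = 50L, vocabularies = vocab)
  expect_error(generate_store(spec, o), "EPHB2", class = "provdash_generation_error")

  bad_vocab <- default_vocabularies()
  bad_vocab[["Cell line"]] <- c(bad_vocab[["Cell line"]], "HeLa")
  expect_error(generate_store(generator_spec(vocabularies = bad_vocab), o),
               "HeLa", class = "provdash_generation_error")
  expect_error(generator_spec(n_experiments = 0), class = "provdash_generation_error")
})

test_that("export/import round-trips the store losslessly", {
  o <- builtin_ontology()
  s <- generate_store(generator_spec(n_projects = 4L, n_experiments = 150L, seed = 5L), o)
  dir <- tempfile("store-")
  export_store(s, dir)
  expect_true(all(file.exists(file.path(
    dir, c("projects.tsv", "experiments.tsv", "mapping.tsv", "store_flat.tsv")
  ))))
  s2 <- import_store(dir)
  expect_identical(s$experiments, s2$experiments)
  expect_identical(s$projects, s2$projects)
  expect_identical(s$mapping, s2$mapping)
  # flat dump has one row per experiment and the mapped columns
  flat <- readr::read_tsv(file.path(dir, "store_flat.tsv"),
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  expect_identical(nrow(flat), 150L)
  expect_true(all(s$mapping$column %in% names(flat)))

  # byte-identical re-export at the same seed
  dir2 <- tempfile("store-")
  export_store(generate_store(generator_spec(n_projects = 4L, n_experiments = 150L, seed = 5L), o), dir2)
  for (f in c("projects.tsv", "experiments.tsv", "store_flat.tsv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})
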