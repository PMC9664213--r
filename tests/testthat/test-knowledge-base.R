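test_that("criterion constructor enforces the PIM/PPO shapes", {
  lexv <- list(table = "unit", row_label = "x")
  expect_error(criterion(
    criterion_id = "X1", part = "non_specific", category = "PIM",
    group = "G", trigger = pred_always(), severity_clauses = list(),
    risk_text = "r", provenance = lexv), class = "pip_kb_error")
  expect_error(criterion(
    criterion_id = "X2", part = "non_specific", category = "PPO",
    group = "G", trigger = pred_always(), risk_text = "r",
    provenance = lexv), class = "pip_kb_error")
  expect_error(criterion(
    criterion_id = "X3", part = "elsewhere", category = "PIM",
    group = "G", trigger = pred_always(),
    severity_clauses = list(list(severity = "avoid",
                                 predicate = pred_always())),
    risk_text = "r", provenance = lexv))
})

test_that("drug_lexicon rejects synonym collisions and duplicate ids", {
  expect_error(drug_lexicon(drugs = list(
    list(canonical_id = "a", label = "A"),
    list(canonical_id = "a", label = "A2"))), class = "pip_kb_error")
  expect_error(drug_lexicon(drugs = list(
    list(canonical_id = "a", label = "Shared name"),
    list(canonical_id = "b", label = "Shared name"))),
    class = "pip_kb_error")
  expect_error(drug_lexicon(
    drugs = list(list(canonical_id = "a", label = "A")),
    classes = list(list(class_id = "c", label = "C",
                        member_ids = "nonexistent"))),
    class = "pip_kb_error")
})

test_that("validate_knowledge_base reports composition and violations", {
  kb <- tiny_kb()
  v <- validate_knowledge_base(kb)
  expect_identical(v$n_criteria, 3L)
  expect_length(v$violations, 0)
  # duplicate provenance row labels are a violation
  kb2 <- kb
  kb2$criteria[[2]]$provenance$row_label <- "T01"
  kb2$criteria[[2]]$provenance$table <- "unit"
  expect_match(validate_knowledge_base(kb2)$violations, "provenance",
               all = FALSE)
})

test_that("count_criteria filters and rejects unknown groups", {
  kb <- tiny_kb()
  expect_identical(count_criteria(kb), 3L)
  expect_identical(count_criteria(kb, part = "non_specific"), 2L)
  expect_identical(count_criteria(kb, category = "PPO"), 1L)
  expect_identical(count_criteria(kb, group = "Test group"), 2L)
  expect_error(count_criteria(kb, group = "No such group"),
               class = "pip_kb_error")
})

test_that("a knowledge base survives the directory round trip", {
  kb <- tiny_kb()
  dir <- withr_like_tempdir <- file.path(tempdir(), "kb-roundtrip")
  unlink(dir, recursive = TRUE)
  save_knowledge_base(kb, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  kb2 <- load_knowledge_base(dir)
  expect_identical(kb_to_list(kb2), kb_to_list(kb))
  unlink(dir, recursive = TRUE)
})

test_that("loading a corrupt knowledge base fails with a kb error", {
  dir <- file.path(tempdir(), "kb-corrupt")
  unlink(dir, recursive = TRUE)
  save_knowledge_base(tiny_kb(), dir)
  # break the criteria file: drop the trigger of the first criterion
  f <- file.path(dir, "criteria_non_specific.json")
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$criteria[[1]]$trigger <- NULL
  jsonlite::write_json(doc, f, auto_unbox = TRUE, null = "null")
  expect_error(load_knowledge_base(dir), class = "pip_kb_error")
  unlink(dir, recursive = TRUE)
})

test_that("the packaged knowledge base loads and validates cleanly", {
  kb <- packaged_kb()
  v <- validate_knowledge_base(kb)
  expect_length(v$violations, 0)
  expect_identical(v$n_criteria, 136L)
})
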