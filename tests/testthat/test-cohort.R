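test_that("cohort generation is deterministic in the seed", {
  kb <- packaged_kb()
  cfg <- cohort_config(n_records = 30, seed = 11,
                       plan = data.frame(criterion_id = "B06",
                                         count_positives = 2,
                                         count_boundary_negatives = 2))
  a <- generate_cohort(cfg, kb)
  b <- generate_cohort(cfg, kb)
  expect_equal(a$records, b$records)
  expect_identical(a$labels, b$labels)
  c2 <- generate_cohort(cohort_config(n_records = 30, seed = 12,
                                      plan = cfg$plan), kb)
  expect_false(isTRUE(all.equal(a$records, c2$records)))
})

test_that("labels mark planted positives and boundary negatives", {
  kb <- packaged_kb()
  cfg <- cohort_config(n_records = 10, seed = 3,
                       plan = data.frame(
                         criterion_id = c("A05", "B21"),
                         count_positives = 1,
                         count_boundary_negatives = 1))
  co <- generate_cohort(cfg, kb)
  expect_identical(length(co$records), 10L)
  expect_identical(nrow(co$labels), 4L)
  expect_setequal(co$labels$expectation, c("flag", "clean"))
  res <- screen_cohort(co$records, kb)
  for (i in seq_len(nrow(co$labels))) {
    lab <- co$labels[i, ]
    hit <- any(res$flags$record_id == lab$record_id &
                 res$flags$criterion_id == lab$criterion_id)
    expect_identical(hit, lab$expectation == "flag",
                     label = paste(lab$record_id, lab$criterion_id))
  }
})

test_that("bad cohort configuration fails with a config error", {
  kb <- packaged_kb()
  expect_error(generate_cohort(
    cohort_config(n_records = 1, seed = 1,
                  plan = data.frame(criterion_id = "A01",
                                    count_positives = 3,
                                    count_boundary_negatives = 3)), kb),
    class = "pip_config_error")
  expect_error(generate_cohort(
    cohort_config(n_records = 10, seed = 1,
                  plan = data.frame(criterion_id = "ZZ99",
                                    count_positives = 1,
                                    count_boundary_negatives = 0)), kb),
    class = "pip_config_error")
})

test_that("write_cohort emits the CSV trio plus labels", {
  kb <- packaged_kb()
  co <- generate_cohort(cohort_config(n_records = 5, seed = 2), kb)
  dir <- file.path(tempdir(), "cohort-out")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("patients.csv", "orders.csv", "procedures.csv",
                    "labels.csv"))
  labels <- read.csv(file.path(dir, "labels.csv"))
  expect_identical(names(labels),
                   c("record_id", "criterion_id", "expectation"))
  unlink(dir, recursive = TRUE)
})

test_that("background records never trigger any criterion", {
  kb <- packaged_kb()
  co <- generate_cohort(cohort_config(n_records = 25, seed = 9), kb)
  res <- screen_cohort(co$records, kb)
  expect_identical(nrow(res$flags), 0L)
})
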