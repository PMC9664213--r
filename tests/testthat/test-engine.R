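test_that("PIM criteria flag with the highest satisfied severity", {
  kb <- tiny_kb()
  # neonate on drugalpha: both clauses satisfied, avoid wins
  neo <- make_record("neo", age_days = 10,
                     orders = list(make_order("drugalpha")))
  res <- screen_record(neo, kb)
  row <- res$flags[res$flags$criterion_id == "T01", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$severity, "avoid")
  expect_identical(row$category, "PIM")
  # toddler: only the always/caution clause fires
  tod <- make_record("tod", age_days = 400,
                     orders = list(make_order("drugalpha")))
  row2 <- screen_record(tod, kb)$flags
  expect_identical(row2$severity[row2$criterion_id == "T01"], "caution")
  # out of the age range: clear
  old <- make_record("old", age_days = 800,
                     orders = list(make_order("drugalpha")))
  expect_false("T01" %in% screen_record(old, kb)$flags$criterion_id)
})

test_that("a satisfied exception suppresses the flag", {
  kb <- tiny_kb()
  over <- make_record("a", age_days = 1000, wt = 10,
                      orders = list(make_order("drugbeta", dose = 100,
                                               freq = 2)))
  expect_true("T02" %in% screen_record(over, kb)$flags$criterion_id)
  exc <- make_record("b", age_days = 1000, wt = 10,
                     diagnoses = "condy",
                     orders = list(make_order("drugbeta", dose = 100,
                                              freq = 2)))
  expect_false("T02" %in% screen_record(exc, kb)$flags$criterion_id)
})

test_that("missing inputs yield indeterminate, not clear or flag", {
  kb <- tiny_kb()
  # per-kg dose threshold but no weight: unscreenable
  nowt <- make_record("c", age_days = 1000, wt = NULL,
                      orders = list(make_order("drugbeta", dose = 100,
                                               freq = 2)))
  res <- screen_record(nowt, kb)
  expect_false("T02" %in% res$flags$criterion_id)
  ind <- res$indeterminate
  expect_true("T02" %in% ind$criterion_id)
  expect_match(ind$missing_inputs[ind$criterion_id == "T02"],
               "current_weight_kg")
})

test_that("PPO criteria flag when the required action is absent", {
  kb <- tiny_kb()
  base <- list(make_order("drugbeta"))
  miss <- make_record("d", age_days = 1000, diagnoses = "condx",
                      orders = base)
  row <- screen_record(miss, kb)$flags
  expect_true("T03" %in% row$criterion_id)
  expect_identical(row$severity[row$criterion_id == "T03"], "omission")
  done <- make_record("e", age_days = 1000, diagnoses = "condx",
                      orders = base,
                      procedures = list(procedure_order(
                        procedure_tag = "checkup",
                        linked_drug_id = "drugbeta")))
  expect_false("T03" %in% screen_record(done, kb)$flags$criterion_id)
  # procedure with the right tag but no recorded drug link: indeterminate
  vague <- make_record("f", age_days = 1000, diagnoses = "condx",
                       orders = base,
                       procedures = list(procedure_order(
                         procedure_tag = "checkup")))
  resv <- screen_record(vague, kb)
  expect_false("T03" %in% resv$flags$criterion_id)
  expect_true("T03" %in% resv$indeterminate$criterion_id)
})

test_that("temporal windows honor their boundaries", {
  t0 <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
  ord <- function(id, drug, at, dur = 1) {
    make_order(drug, order_id = id, start_time = at, duration_days = dur)
  }
  w48 <- temporal_window("within_after", after_hours = 48)
  a <- ord("a", "drugalpha", t0)
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 + 48 * 3600), w48)$status,
    "satisfied")
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 + 49 * 3600), w48)$status,
    "not_satisfied")
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 - 1 * 3600), w48)$status,
    "not_satisfied")
  gap <- temporal_window("required_gap_before_and_after",
                         before_hours = 2, after_hours = 6)
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 - 3 * 3600), gap)$status,
    "satisfied")
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 + 2 * 3600), gap)$status,
    "not_satisfied")
  expect_identical(
    within_window(a, ord("b", "drugbeta", t0 - 6 * 3600), gap)$status,
    "not_satisfied")
  sim <- temporal_window("simultaneous")
  expect_identical(
    within_window(ord("a", "drugalpha", t0, dur = 5),
                  ord("b", "drugbeta", t0 + 72 * 3600, dur = 1), sim)$status,
    "satisfied")
  expect_identical(
    within_window(ord("a", "drugalpha", t0, dur = 1),
                  ord("b", "drugbeta", t0 + 72 * 3600, dur = 1), sim)$status,
    "not_satisfied")
  # no timing information at all: treated as simultaneous
  expect_identical(
    within_window(ord("a", "drugalpha", NULL), ord("b", "drugbeta", NULL),
                  sim)$status, "satisfied")
  # one-sided timing: indeterminate
  expect_identical(
    within_window(ord("a", "drugalpha", t0), ord("b", "drugbeta", NULL),
                  sim)$status, "indeterminate")
})

test_that("screen_cohort aggregates and rejects duplicate record ids", {
  kb <- tiny_kb()
  r1 <- make_record("r1", age_days = 10,
                    orders = list(make_order("drugalpha")))
  r2 <- make_record("r2", age_days = 3000,
                    orders = list(make_order("benigndrug")))
  res <- screen_cohort(list(r1, r2), kb)
  expect_identical(res$summary$n_records, 2L)
  expect_identical(res$summary$n_flagged, 1L)
  expect_equal(res$summary$prevalence, 0.5)
  expect_error(screen_cohort(list(r1, r1), kb), class = "pip_input_error")
})

test_that("packaged criteria match their encoded boundary semantics", {
  kb <- packaged_kb()
  # neonate window is 0..28 days inclusive
  d29 <- make_record("x", age_days = 29,
                     orders = list(make_order("ceftriaxone",
                                              route = "intravenous")))
  expect_false("B06" %in% screen_record(d29, kb)$flags$criterion_id)
  d28 <- make_record("y", age_days = 28,
                     orders = list(make_order("ceftriaxone",
                                              route = "intravenous")))
  expect_true("B06" %in% screen_record(d28, kb)$flags$criterion_id)
})
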