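test_that("patient_profile requires exactly one age anchor", {
  expect_error(patient_profile(patient_id = "p", sex = "male"),
               class = "pip_input_error")
  expect_error(
    patient_profile(patient_id = "p", sex = "male",
                    birth_date = as.Date("2023-01-01"),
                    age_days_at_encounter = 100),
    class = "pip_input_error")
  p <- patient_profile(patient_id = "p", sex = "female",
                       age_days_at_encounter = 100)
  expect_identical(p$age_days_at_encounter, 100L)
})

test_that("derive_age_profile computes days, neonate and prematurity", {
  p <- patient_profile(patient_id = "p", sex = "male",
                       birth_date = as.Date("2024-02-10"))
  a <- derive_age_profile(p, as.Date("2024-03-01"))
  expect_identical(a$postnatal_days, 20L)
  expect_true(a$is_neonate)
  expect_true(is.na(a$is_premature))
  p2 <- patient_profile(patient_id = "p", sex = "male",
                        age_days_at_encounter = 29,
                        gestational_age_weeks = 30)
  a2 <- derive_age_profile(p2, as.Date("2024-03-01"))
  expect_false(a2$is_neonate)
  expect_true(a2$is_premature)
})

test_that("derive_dose_profile names its missing inputs", {
  p_nowt <- patient_profile(patient_id = "p", sex = "male",
                            age_days_at_encounter = 400)
  o <- make_order("drugalpha", dose = 100, freq = NULL,
                  duration_days = NULL)
  d <- derive_dose_profile(o, p_nowt)
  expect_identical(d$mg_per_dose, 100)
  expect_true(is.na(d$mg_per_day))
  expect_true(is.na(d$mg_per_kg_per_day))
  expect_true(is.na(d$cumulative_mg))
  expect_setequal(d$missing_inputs,
                  c("frequency_per_day", "current_weight_kg",
                    "cumulative_dose"))
  # full information: all rates derived, cumulative falls back to
  # dose x freq x duration
  p_wt <- patient_profile(patient_id = "p", sex = "male",
                          age_days_at_encounter = 400,
                          current_weight_kg = 10)
  o2 <- make_order("drugalpha", dose = 50, freq = 2, duration_days = 4)
  d2 <- derive_dose_profile(o2, p_wt)
  expect_identical(d2$mg_per_day, 100)
  expect_identical(d2$mg_per_kg_per_day, 10)
  expect_identical(d2$cumulative_mg, 400)
  expect_true(d2$cumulative_derived)
  # explicit cumulative dose wins over the fallback
  o3 <- make_order("drugalpha", dose = 50, freq = 2, duration_days = 4,
                   cumulative_dose = 30, cumulative_unit = "g")
  expect_identical(derive_dose_profile(o3, p_wt)$cumulative_mg, 30000)
})

test_that("canonicalize_drug maps synonyms case-insensitively", {
  lex <- tiny_lexicon()
  expect_identical(canonicalize_drug("Drugalpha", lex), "drugalpha")
  expect_identical(canonicalize_drug("  ALPHADRUG ", lex), "drugalpha")
  expect_true(is.na(canonicalize_drug("aspirin-like", lex)))
})

test_that("packaged lexicon resolves common synonyms", {
  kb <- packaged_kb()
  expect_identical(canonicalize_drug("paracetamol", kb$lexicon),
                   "acetaminophen")
  expect_identical(canonicalize_drug("sodium valproate", kb$lexicon),
                   "valproic_acid")
})
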