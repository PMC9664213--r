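test_that("predicate constructors validate their arguments", {
  expect_error(pred_age_in_range(10, 5))
  expect_error(pred_age_in_range(-1, 5))
  expect_error(dose_exceeds("per_lightyear", 5))
  expect_error(duration_exceeds(3, "fortnights"))
  expect_error(pred_sex_is("other"))
  expect_error(temporal_window("sometimes"))
  p <- pred_drug_present("drugalpha", route = "oral", freq_above = 2)
  expect_s3_class(p, "pip_predicate")
  expect_identical(p$freq_above, 2L)
})

test_that("years_to_days uses the ceiling convention", {
  expect_identical(years_to_days(1), 366L)
  expect_identical(years_to_days(2), 731L)
  expect_identical(years_to_days(18), 6575L)
})

test_that("validate_predicate catches unknown drugs, tags and shapes", {
  lex <- tiny_lexicon()
  voc <- tiny_vocabulary()
  ok <- pred_all_of(pred_drug_present("alphabeta"),
                    pred_diagnosis_present("condx"))
  expect_length(validate_predicate(ok, lex, voc, "t"), 0)
  bad_drug <- pred_drug_present("nosuchdrug")
  expect_match(validate_predicate(bad_drug, lex, voc, "t"),
               "nosuchdrug", all = FALSE)
  bad_tag <- pred_diagnosis_present("nosuchtag")
  expect_match(validate_predicate(bad_tag, lex, voc, "t"),
               "nosuchtag", all = FALSE)
})

test_that("predicates survive a list round trip identically", {
  p <- pred_any_of(
    pred_all_of(pred_age_in_range(0, 731),
                pred_drug_present("drugalpha",
                                  dose = dose_exceeds("per_kg_per_day", 10),
                                  min_duration = duration_exceeds(48, "hours"),
                                  route = c("oral", "intravenous"))),
    pred_not(pred_procedure_present("checkup", linked_drug = "drugbeta")),
    pred_co_prescribed(anchor = "drugalpha", drug = "drugbeta",
                       window = temporal_window("within_after",
                                                after_hours = 48)))
  expect_identical(predicate_from_list(predicate_to_list(p)), p)
  # and through actual JSON text, as in the packaged knowledge base
  json <- jsonlite::toJSON(predicate_to_list(p), auto_unbox = TRUE,
                           digits = NA, null = "null")
  back <- predicate_from_list(jsonlite::fromJSON(json,
                                                 simplifyVector = FALSE))
  expect_identical(back, p)
})
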