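# Shared fixtures: the packaged knowledge base (loaded once per session)
# and a small hand-built knowledge base for unit tests.

.fixture_env <- new.env(parent = emptyenv())

packaged_kb <- function() {
  if (is.null(.fixture_env$kb)) {
    .fixture_env$kb <- load_knowledge_base(pip_kb_path())
  }
  .fixture_env$kb
}

tiny_lexicon <- function() {
  drug_lexicon(
    drugs = list(
      list(canonical_id = "drugalpha", label = "Drugalpha",
           synonyms = "alphadrug"),
      list(canonical_id = "drugbeta", label = "Drugbeta"),
      list(canonical_id = "druggamma", label = "Druggamma"),
      list(canonical_id = "benigndrug", label = "Benigndrug")
    ),
    classes = list(
      list(class_id = "alphabeta", label = "Alpha-beta class",
           member_ids = c("drugalpha", "drugbeta"))
    )
  )
}

tiny_vocabulary <- function() {
  condition_vocabulary(data.frame(
    tag_id = c("condx", "condy", "checkup"),
    label = c("Condition X", "Condition Y", "Check-up performed"),
    stringsAsFactors = FALSE))
}

tiny_kb <- function() {
  lex <- tiny_lexicon()
  voc <- tiny_vocabulary()
  crit <- list(
    criterion(
      criterion_id = "T01", part = "non_specific", category = "PIM",
      group = "Test group",
      trigger = pred_all_of(pred_age_in_range(0, 730),
                            pred_drug_present("drugalpha")),
      severity_clauses = list(
        list(severity = "avoid", predicate = pred_age_in_range(0, 29)),
        list(severity = "caution", predicate = pred_always())),
      risk_text = "Test risk A.",
      provenance = list(table = "unit", row_label = "T01")),
    criterion(
      criterion_id = "T02", part = "non_specific", category = "PIM",
      group = "Test group",
      trigger = pred_all_of(
        pred_age_in_range(0, 6575),
        pred_drug_present("alphabeta",
                          dose = dose_exceeds("per_kg_per_day", 10))),
      exception = pred_diagnosis_present("condy"),
      severity_clauses = list(
        list(severity = "caution", predicate = pred_always())),
      risk_text = "Test risk B.",
      provenance = list(table = "unit", row_label = "T02")),
    criterion(
      criterion_id = "T03", part = "specific", category = "PPO",
      group = "Test problems", subgroup = "Subtest",
      trigger = pred_all_of(pred_age_in_range(0, 6575),
                            pred_diagnosis_present("condx"),
                            pred_drug_present("drugbeta")),
      required_action = pred_procedure_present("checkup",
                                               linked_drug = "drugbeta"),
      risk_text = "Test risk C.",
      provenance = list(table = "unit", row_label = "T03"))
  )
  knowledge_base(version = "0.0.1", criteria = crit, lexicon = lex,
                 vocabulary = voc)
}

# A minimal record builder used across tests.
make_record <- function(record_id = "r1", age_days = 400, sex = "unknown",
                        ga = NULL, bw = NULL, wt = 10,
                        diagnoses = character(), flags = character(),
                        orders = list(), procedures = list(),
                        encounter_date = as.Date("2024-03-01")) {
  prescription_record(
    record_id = record_id, encounter_date = encounter_date,
    patient = patient_profile(
      patient_id = paste0("pat-", record_id), sex = sex,
      age_days_at_encounter = age_days, gestational_age_weeks = ga,
      birth_weight_g = bw, current_weight_kg = wt,
      diagnosis_tags = diagnoses, clinical_flags = flags),
    orders = orders, procedures = procedures)
}

make_order <- function(drug_id, order_id = paste0("o-", drug_id),
                       dose = 50, dose_unit = "mg", freq = 2,
                       route = "oral", start_time = NULL,
                       duration_days = 5, cumulative_dose = NULL,
                       cumulative_unit = "mg") {
  medication_order(
    order_id = order_id, drug_text = drug_id, drug_id = drug_id,
    dose_amount = dose, dose_unit = dose_unit, frequency_per_day = freq,
    route = route, start_time = start_time, duration_days = duration_days,
    cumulative_dose = cumulative_dose, cumulative_unit = cumulative_unit)
}
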