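#' Patient, order and record constructors
#'
#' A prescription record is one patient encounter: demographics, diagnosis
#' and clinical-context tags, medication orders and procedure orders. These
#' are the inputs the screening engine evaluates criteria against. Missing
#' optional fields (weight, timestamps, routes, gestational age) do not
#' invalidate a record; predicates needing them become indeterminate.
#'
#' @param patient_id,record_id,order_id Identifiers.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param birth_date `Date` of birth, or `NULL` when `age_days_at_encounter`
#'   is supplied (exactly one of the two must be given).
#' @param age_days_at_encounter Postnatal age in whole days at the encounter.
#' @param gestational_age_weeks Gestational age at birth, weeks (optional).
#' @param birth_weight_g Birth weight in grams (optional).
#' @param current_weight_kg Current weight in kilograms (optional).
#' @param diagnosis_tags,clinical_flags Character vectors of
#'   condition-vocabulary tag ids.
#' @return `patient_profile()` returns a `pip_patient` object.
#' @export
patient_profile <- function(patient_id, sex = "unknown", birth_date = NULL,
                            age_days_at_encounter = NULL,
                            gestational_age_weeks = NULL,
                            birth_weight_g = NULL, current_weight_kg = NULL,
                            diagnosis_tags = character(),
                            clinical_flags = character()) {
  if (is.null(birth_date) == is.null(age_days_at_encounter)) {
    pip_abort("supply exactly one of birth_date / age_days_at_encounter",
              "pip_input_error")
  }
  if (!is.null(current_weight_kg) && current_weight_kg <= 0)
    pip_abort("current_weight_kg must be positive", "pip_input_error")
  if (!is.null(birth_weight_g) && birth_weight_g <= 0)
    pip_abort("birth_weight_g must be positive", "pip_input_error")
  structure(list(
    patient_id = patient_id,
    sex = match.arg(sex, c("unknown", "male", "female")),
    birth_date = birth_date,
    age_days_at_encounter =
      if (!is.null(age_days_at_encounter)) as.integer(age_days_at_encounter),
    gestational_age_weeks = gestational_age_weeks,
    birth_weight_g = birth_weight_g,
    current_weight_kg = current_weight_kg,
    diagnosis_tags = as.character(diagnosis_tags),
    clinical_flags = as.character(clinical_flags)
  ), class = "pip_patient")
}

ORDER_ROUTES <- c("oral", "intravenous", "intramuscular", "nasal", "topical",
                  "rectal", "ophthalmic", "inhaled", "other")

#' @rdname patient_profile
#' @param drug_text Drug name as written on the order.
#' @param drug_id Canonical id after lexicon resolution (`NA` when unknown).
#' @param dose_amount Dose per administration (numeric, >= 0).
#' @param dose_unit Mass unit of `dose_amount` (`"mg"`, `"g"`, `"ug"`).
#' @param frequency_per_day Administrations per day (integer >= 1, optional).
#' @param route Administration route, one of the modeled routes (optional).
#' @param start_time `POSIXct` start of treatment (optional).
#' @param duration_days Treatment duration in days (optional).
#' @param cumulative_dose,cumulative_unit Explicit cumulative exposure
#'   (optional; otherwise derived as dose x frequency x duration).
#' @return `medication_order()` returns a `pip_order` object.
#' @export
medication_order <- function(order_id, drug_text, drug_id = NA_character_,
                             dose_amount = 0, dose_unit = "mg",
                             frequency_per_day = NULL, route = NULL,
                             start_time = NULL, duration_days = NULL,
                             cumulative_dose = NULL, cumulative_unit = "mg") {
  stopifnot(dose_amount >= 0)
  if (!is.null(frequency_per_day)) {
    frequency_per_day <- as.integer(frequency_per_day)
    stopifnot(frequency_per_day >= 1)
  }
  if (!is.null(route)) route <- match.arg(route, ORDER_ROUTES)
  structure(list(
    order_id = as.character(order_id), drug_text = drug_text,
    drug_id = drug_id, dose_amount = as.numeric(dose_amount),
    dose_unit = dose_unit, frequency_per_day = frequency_per_day,
    route = route, start_time = start_time,
    duration_days = if (!is.null(duration_days)) as.numeric(duration_days),
    cumulative_dose = if (!is.null(cumulative_dose)) as.numeric(cumulative_dose),
    cumulative_unit = cumulative_unit
  ), class = "pip_order")
}

#' @rdname patient_profile
#' @param procedure_tag Vocabulary tag of the procedure (e.g. `"tdm"`,
#'   `"skin_test"`).
#' @param linked_drug_id Drug or class the procedure refers to (optional).
#' @param time `POSIXct` time of the procedure (optional).
#' @return `procedure_order()` returns a `pip_procedure` object.
#' @export
procedure_order <- function(procedure_tag, linked_drug_id = NULL, time = NULL) {
  structure(list(procedure_tag = procedure_tag,
                 linked_drug_id = linked_drug_id, time = time),
            class = "pip_procedure")
}

#' @rdname patient_profile
#' @param encounter_date `Date` of the encounter.
#' @param patient A [patient_profile()].
#' @param orders List of [medication_order()]s.
#' @param procedures List of [procedure_order()]s.
#' @return `prescription_record()` returns a `pip_record` object.
#' @export
prescription_record <- function(record_id, encounter_date, patient,
                                orders = list(), procedures = list()) {
  structure(list(record_id = as.character(record_id),
                 encounter_date = encounter_date, patient = patient,
                 orders = orders, procedures = procedures),
            class = "pip_record")
}

#' Derive the age quantities the criteria reason about
#'
#' @param patient A [patient_profile()].
#' @param at `Date` at which to compute the age (the encounter date).
#' @return A list with `postnatal_days`, `age_years`
#'   (`postnatal_days / 365.25`), `is_neonate` (postnatal age <= 28 days)
#'   and `is_premature` (`TRUE`/`FALSE`/`NA`; gestational age at birth
#'   < 37 weeks, `NA` when the gestational age is unrecorded).
#' @export
derive_age_profile <- function(patient, at) {
  days <- if (!is.null(patient$age_days_at_encounter)) {
    patient$age_days_at_encounter
  } else {
    as.integer(as.Date(at) - as.Date(patient$birth_date))
  }
  if (is.na(days) || days < 0) {
    pip_abort("derived age is negative or undefined", "pip_input_error")
  }
  ga <- patient$gestational_age_weeks
  list(
    postnatal_days = as.integer(days),
    age_years = days / 365.25,
    is_neonate = days <= 28L,
    is_premature = if (is.null(ga)) NA else ga < 37
  )
}

#' Derive normalized dose rates for one order
#'
#' Converts the order's dose to milligrams and derives the rates the
#' criteria thresholds are written in. Fields whose inputs are missing are
#' `NA` and the missing input is named in `missing_inputs`. The hourly rate
#' assumes the daily amount is delivered over 24 h (continuous infusion,
#' the setting in which per-hour thresholds are written). The cumulative
#' exposure uses the order's explicit cumulative dose when present, else
#' falls back to dose x frequency x duration; the fallback is marked with
#' `cumulative_derived = TRUE`.
#'
#' @param order A [medication_order()].
#' @param patient A [patient_profile()] (supplies the current weight).
#' @return A list with `mg_per_dose`, `mg_per_day`, `mg_per_kg_per_day`,
#'   `mg_per_kg_per_hour`, `cumulative_mg`, `cumulative_mg_per_kg`,
#'   `cumulative_derived` and `missing_inputs`.
#' @export
derive_dose_profile <- function(order, patient) {
  missing_inputs <- character()
  wt <- patient$current_weight_kg
  freq <- order$frequency_per_day

  mg_per_dose <- mass_to_mg(order$dose_amount, order$dose_unit)
  if (is.null(freq)) {
    mg_per_day <- NA_real_
    missing_inputs <- c(missing_inputs, "frequency_per_day")
  } else {
    mg_per_day <- mg_per_dose * freq
  }
  if (is.null(wt)) {
    mg_per_kg_per_day <- NA_real_
    mg_per_kg_per_hour <- NA_real_
    missing_inputs <- c(missing_inputs, "current_weight_kg")
  } else {
    mg_per_kg_per_day <- mg_per_day / wt
    mg_per_kg_per_hour <- mg_per_day / wt / 24
  }

  cumulative_derived <- FALSE
  if (!is.null(order$cumulative_dose)) {
    cumulative_mg <- mass_to_mg(order$cumulative_dose,
                                order$cumulative_unit %||% "mg")
  } else if (!is.null(freq) && !is.null(order$duration_days)) {
    cumulative_mg <- mg_per_dose * freq * order$duration_days
    cumulative_derived <- TRUE
  } else {
    cumulative_mg <- NA_real_
    missing_inputs <- c(missing_inputs, "cumulative_dose")
  }
  cumulative_mg_per_kg <- if (is.null(wt)) NA_real_ else cumulative_mg / wt

  list(mg_per_dose = mg_per_dose, mg_per_day = mg_per_day,
       mg_per_kg_per_day = mg_per_kg_per_day,
       mg_per_kg_per_hour = mg_per_kg_per_hour,
       cumulative_mg = cumulative_mg,
       cumulative_mg_per_kg = cumulative_mg_per_kg,
       cumulative_derived = cumulative_derived,
       missing_inputs = unique(missing_inputs))
}

#' Resolve a written drug name to its canonical lexicon id
#'
#' Matching is an exact, case-insensitive, whitespace-trimmed synonym
#' lookup. Unknown names return `NA_character_` rather than raising, so a
#' record with an unrecognized drug stays screenable; unknown drugs never
#' match any criterion.
#'
#' @param text Drug name as written.
#' @param lexicon A [drug_lexicon()].
#' @return Canonical drug id, or `NA_character_` when unknown.
#' @export
canonicalize_drug <- function(text, lexicon) {
  key <- tolower(trimws(text))
  id <- lexicon$synonym_map[[key]]
  if (is.null(id)) NA_character_ else id
}
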