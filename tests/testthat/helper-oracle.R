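# Independent brute-force oracle for criterion evaluation.
#
# This evaluator is written from the documented semantics, deliberately
# not sharing code with the engine: three-valued logic is represented
# numerically (true = 1, unknown = 0.5, false = 0) so that all_of is
# `min`, any_of is `max` and not is `1 - v` (strong Kleene), and every
# atom is evaluated by explicit loops over the record's raw fields.

o_true <- 1; o_unk <- 0.5; o_false <- 0

o_mg <- function(x, unit) {
  f <- c(mg = 1, g = 1000, ug = 0.001, mcg = 0.001,
         "µg" = 0.001, "μg" = 0.001)[[tolower(unit)]]
  x * f
}

o_days <- function(value, unit) {
  value * c(hours = 1 / 24, days = 1, weeks = 7, months = 30.44)[[unit]]
}

o_age_days <- function(rec) {
  p <- rec$patient
  if (!is.null(p$age_days_at_encounter)) return(p$age_days_at_encounter)
  as.integer(as.Date(rec$encounter_date) - as.Date(p$birth_date))
}

o_members <- function(kb, id) resolve_drug_ids(kb$lexicon, id)

# One order against a drug_present atom -> 0 / 0.5 / 1.
o_order_match <- function(o, p, members, rec) {
  did <- o$drug_id
  if (is.null(did) || is.na(did) || !(did %in% members)) return(o_false)
  vals <- o_true
  if (!is.null(p$route)) {
    vals <- c(vals, if (is.null(o$route)) o_unk
              else if (o$route %in% p$route) o_true else o_false)
  }
  if (!is.null(p$dose)) {
    wt <- rec$patient$current_weight_kg
    mg_dose <- o_mg(o$dose_amount, o$dose_unit)
    mg_day <- if (is.null(o$frequency_per_day)) NA_real_
              else mg_dose * o$frequency_per_day
    cum <- if (!is.null(o$cumulative_dose)) {
      o_mg(o$cumulative_dose, if (is.null(o$cumulative_unit)) "mg"
           else o$cumulative_unit)
    } else if (!is.null(o$frequency_per_day) && !is.null(o$duration_days)) {
      mg_dose * o$frequency_per_day * o$duration_days
    } else NA_real_
    v <- switch(p$dose$metric,
      per_dose = mg_dose,
      per_day = mg_day,
      per_kg_per_day = if (is.null(wt)) NA_real_ else mg_day / wt,
      per_kg_per_hour = if (is.null(wt)) NA_real_ else mg_day / wt / 24,
      cumulative_total = cum,
      cumulative_per_kg = if (is.null(wt)) NA_real_ else cum / wt)
    thr <- o_mg(p$dose$threshold, p$dose$unit)
    vals <- c(vals, if (is.na(v)) o_unk
              else if (if (isTRUE(p$dose$inclusive)) v >= thr else v > thr)
                o_true else o_false)
  }
  if (!is.null(p$min_duration)) {
    thr <- o_days(p$min_duration$value, p$min_duration$unit)
    vals <- c(vals, if (is.null(o$duration_days)) o_unk
              else if (o$duration_days > thr) o_true else o_false)
  }
  if (!is.null(p$freq_below) || !is.null(p$freq_above)) {
    f <- o$frequency_per_day
    vals <- c(vals, if (is.null(f)) o_unk
              else if ((is.null(p$freq_below) || f < p$freq_below) &&
                       (is.null(p$freq_above) || f > p$freq_above))
                o_true else o_false)
  }
  min(vals)
}

o_window <- function(a, b, w) {
  if (is.null(a$start_time) && is.null(b$start_time)) {
    delta <- 0
    overlap <- TRUE
  } else if (is.null(a$start_time) || is.null(b$start_time)) {
    return(o_unk)
  } else {
    delta <- as.numeric(difftime(a$start_time, b$start_time, units = "hours"))
    da <- (if (is.null(a$duration_days)) 1 else a$duration_days) * 24
    db <- (if (is.null(b$duration_days)) 1 else b$duration_days) * 24
    overlap <- (delta <= db) && (-delta <= da)
  }
  hit <- switch(w$relation,
    within_after = -delta >= 0 && -delta <= w$after_hours,
    within_before = delta >= 0 && delta <= w$before_hours,
    simultaneous = overlap,
    required_gap_before_and_after =
      delta > -w$before_hours && delta < w$after_hours)
  if (hit) o_true else o_false
}

o_atom <- function(p, rec, kb) {
  tags <- unique(c(rec$patient$diagnosis_tags, rec$patient$clinical_flags))
  switch(p$kind,
    always = o_true,
    age_in_range = {
      d <- o_age_days(rec)
      if (d >= p$min_days && d < p$max_days) o_true else o_false
    },
    gestational_age_below = {
      ga <- rec$patient$gestational_age_weeks
      if (is.null(ga)) o_unk else if (ga < p$weeks) o_true else o_false
    },
    birth_weight_below = {
      bw <- rec$patient$birth_weight_g
      if (is.null(bw)) o_unk else if (bw < p$grams) o_true else o_false
    },
    current_weight_below = {
      wt <- rec$patient$current_weight_kg
      if (is.null(wt)) o_unk else if (wt < p$kg) o_true else o_false
    },
    is_premature = {
      ga <- rec$patient$gestational_age_weeks
      if (is.null(ga)) o_unk else if (ga < 37) o_true else o_false
    },
    sex_is = {
      s <- rec$patient$sex
      if (s == "unknown") o_unk else if (s == p$sex) o_true else o_false
    },
    diagnosis_present = if (p$tag %in% tags) o_true else o_false,
    any_medication_present =
      if (length(rec$orders) > 0) o_true else o_false,
    drug_count_at_least = {
      members <- o_members(kb, p$drug)
      ids <- character()
      for (o in rec$orders) {
        if (!is.null(o$drug_id) && !is.na(o$drug_id) &&
            o$drug_id %in% members) {
          ids <- union(ids, o$drug_id)
        }
      }
      if (length(ids) >= p$n) o_true else o_false
    },
    drug_present = {
      members <- o_members(kb, p$drug)
      v <- o_false
      for (o in rec$orders) v <- max(v, o_order_match(o, p, members, rec))
      v
    },
    co_prescribed = {
      am <- o_members(kb, p$anchor)
      cm <- o_members(kb, p$drug)
      inm <- function(o, m) !is.null(o$drug_id) && !is.na(o$drug_id) &&
        o$drug_id %in% m
      v <- o_false
      for (a in rec$orders) {
        if (!inm(a, am)) next
        for (b in rec$orders) {
          if (!inm(b, cm) || identical(a$order_id, b$order_id)) next
          rv <- if (is.null(p$route)) o_true
                else if (is.null(b$route)) o_unk
                else if (b$route %in% p$route) o_true else o_false
          v <- max(v, min(rv, o_window(a, b, p$window)))
        }
      }
      v
    },
    procedure_present = {
      v <- o_false
      for (pr in rec$procedures) {
        if (!identical(pr$procedure_tag, p$tag)) next
        if (is.null(p$linked_drug)) { v <- o_true; next }
        members <- o_members(kb, p$linked_drug)
        v <- max(v, if (is.null(pr$linked_drug_id)) o_unk
                 else if (pr$linked_drug_id %in% members ||
                          identical(pr$linked_drug_id, p$linked_drug))
                   o_true else o_false)
      }
      v
    },
    stop("oracle: unknown atom kind ", p$kind)
  )
}

o_eval <- function(p, rec, kb) {
  switch(p$kind,
    all_of = min(vapply(p$children, o_eval, numeric(1), rec = rec, kb = kb)),
    any_of = max(vapply(p$children, o_eval, numeric(1), rec = rec, kb = kb)),
    not = 1 - o_eval(p$child, rec, kb),
    o_atom(p, rec, kb)
  )
}

# All criterion ids the oracle says must be flagged on this record.
oracle_flags <- function(rec, kb) {
  out <- character()
  for (cr in kb$criteria) {
    t <- o_eval(cr$trigger, rec, kb)
    if (t != o_true) next
    e <- if (is.null(cr$exception)) o_false
         else o_eval(cr$exception, rec, kb)
    if (e != o_false) next
    hit <- if (cr$category == "PIM") {
      any(vapply(cr$severity_clauses, function(sc)
        o_eval(sc$predicate, rec, kb), numeric(1)) == o_true)
    } else {
      o_eval(cr$required_action, rec, kb) == o_false
    }
    if (hit) out <- c(out, cr$criterion_id)
  }
  out
}

# Random record generator for the oracle-equivalence property. Uses the
# session RNG (seeded by the caller); draws drugs from the packaged
# lexicon and tags from the vocabulary, with deliberate gaps (missing
# weight, routes, timestamps) to exercise the indeterminate paths.
random_record <- function(kb, record_id) {
  lex <- kb$lexicon
  voc_tags <- kb$vocabulary$tags$tag_id
  age <- sample(c(0:60, sample(61:6574, 30)), 1)
  n_orders <- sample(0:5, 1)
  drugs <- if (n_orders > 0) sample(lex$drug_ids, n_orders) else character()
  base_time <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
  orders <- lapply(seq_along(drugs), function(i) {
    medication_order(
      order_id = sprintf("%s-o%d", record_id, i),
      drug_text = drugs[i], drug_id = drugs[i],
      dose_amount = round(stats::runif(1, 1, 800), 1),
      dose_unit = sample(c("mg", "mg", "g", "ug"), 1),
      frequency_per_day = if (stats::runif(1) < 0.8) sample(1:6, 1),
      route = if (stats::runif(1) < 0.85)
        sample(c("oral", "intravenous", "topical", "inhaled", "nasal",
                 "rectal", "ophthalmic", "intramuscular"), 1),
      start_time = if (stats::runif(1) < 0.7)
        base_time + sample(-96:96, 1) * 3600,
      duration_days = if (stats::runif(1) < 0.8)
        sample(c(1:30, 45, 70, 200, 400), 1),
      cumulative_dose = if (stats::runif(1) < 0.15)
        round(stats::runif(1, 100, 40000)),
      cumulative_unit = "mg")
  })
  n_tags <- sample(0:4, 1)
  n_procs <- sample(0:2, 1)
  procs <- lapply(seq_len(n_procs), function(i) {
    procedure_order(
      procedure_tag = sample(c("tdm", "skin_test", "cyp2d6_test",
                               "pharmacogenetic_test",
                               "repeat_dose_scheduled"), 1),
      linked_drug_id = if (stats::runif(1) < 0.6)
        sample(lex$drug_ids, 1))
  })
  prescription_record(
    record_id = record_id, encounter_date = as.Date("2024-03-01"),
    patient = patient_profile(
      patient_id = paste0("pat-", record_id),
      sex = sample(c("male", "female", "unknown"), 1),
      age_days_at_encounter = age,
      gestational_age_weeks = if (stats::runif(1) < 0.5)
        sample(26:42, 1),
      birth_weight_g = if (stats::runif(1) < 0.5)
        sample(600:4500, 1),
      current_weight_kg = if (stats::runif(1) < 0.8)
        round(stats::runif(1, 0.7, 70), 1),
      diagnosis_tags = if (n_tags > 0) sample(voc_tags, n_tags)
        else character()),
    orders = orders, procedures = procs)
}
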