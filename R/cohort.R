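#' Synthetic pediatric prescription cohorts with planted ground truth
#'
#' The generator builds prescription records directly from a criterion's
#' predicate tree: a planted positive satisfies the trigger, leaves the
#' exception definitely unsatisfied and (for a PPO) omits the required
#' action, while a boundary negative is the same construction with the
#' decisive numeric quantity moved to the non-flagging side of its
#' threshold (a dose at exactly a strict `>` cutoff, an age at the first
#' excluded day, a co-prescription just outside its window). Background
#' records draw from a benign drug pool verified non-triggering at
#' generation time, so ground-truth labels are exactly interpretable.
#' All sampling runs on a private linear congruential generator, so a
#' cohort is a pure function of its configuration and seed.
#'
#' @name synthetic-cohort
#' @keywords internal
NULL

# Private deterministic RNG (LCG, modulus 2^31): cohorts must be
# byte-identical across platforms and independent of the global RNG state.
lcg_new <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- (abs(as.numeric(seed)) + 11) %% 2147483648
  env
}
lcg_next <- function(rng) {
  rng$state <- (1103515245 * rng$state + 12345) %% 2147483648
  rng$state
}
lcg_int <- function(rng, n) as.integer(lcg_next(rng) %% n)          # 0..n-1
lcg_unif <- function(rng) lcg_next(rng) / 2147483648

# Reference weight-for-age used when no weight constraint applies.
default_weight_kg <- function(age_days) {
  yrs <- age_days / 365.25
  if (age_days <= 28) 3.4
  else if (yrs < 1) round(3.5 + 0.5 * (age_days / 30.44), 1)
  else if (yrs <= 12) round(2 * yrs + 8, 1)
  else round(40 + 2 * (yrs - 12), 1)
}

new_plan_env <- function() {
  env <- new.env(parent = emptyenv())
  env$age_lo <- 0L
  env$age_hi <- years_to_days(18)
  env$ga <- NULL; env$bw <- NULL; env$wt <- NULL; env$sex <- NULL
  env$tags <- character()
  env$procedures <- list()
  env$orders <- list()      # order specs
  env$flips <- list()       # boundary-flip candidates: list(priority, apply)
  env$need_any_med <- FALSE
  env
}

add_flip <- function(env, priority, apply_fn, bound = NA_real_) {
  env$flips[[length(env$flips) + 1L]] <- list(priority = priority,
                                              apply = apply_fn,
                                              bound = bound)
}

find_or_new_order <- function(env, drug_id) {
  for (i in seq_along(env$orders)) {
    if (identical(env$orders[[i]]$drug_id, drug_id) &&
        !isTRUE(env$orders[[i]]$exclusive)) return(i)
  }
  env$orders[[length(env$orders) + 1L]] <- list(
    drug_id = drug_id, route = NULL, dose = NULL, dose_mult = 1.25,
    min_duration = NULL, duration_mult = 1.5, freq = NULL,
    offset_hours = 0, exclusive = FALSE, far_apart = FALSE)
  length(env$orders)
}

pick_member <- function(lexicon, id, rng) {
  members <- resolve_drug_ids(lexicon, id)
  members[lcg_int(rng, length(members)) + 1L]
}

# Satisfy a drug_present atom: create a dedicated order spec carrying the
# atom's constraints (route/dose/duration/frequency on the same order).
satisfy_drug_atom <- function(p, env, kb, rng) {
  drug_id <- pick_member(kb$lexicon, p$drug, rng)
  spec <- list(drug_id = drug_id,
               route = if (!is.null(p$route)) p$route[[1]],
               dose = p$dose, dose_mult = 1.25,
               min_duration = p$min_duration, duration_mult = 1.5,
               freq = NULL, offset_hours = 0,
               exclusive = TRUE, far_apart = FALSE)
  if (!is.null(p$freq_below)) spec$freq <- max(1L, p$freq_below - 1L)
  if (!is.null(p$freq_above)) spec$freq <- p$freq_above + 1L
  env$orders[[length(env$orders) + 1L]] <- spec
  idx <- length(env$orders)
  if (!is.null(p$dose)) {
    add_flip(env, 1, local({
      i <- idx; inclusive <- isTRUE(p$dose$inclusive)
      function(env) {
        env$orders[[i]]$dose_mult <- if (inclusive) 0.99 else 1.0
        env
      }
    }))
  }
  if (!is.null(p$min_duration)) {
    add_flip(env, 2, local({
      i <- idx
      function(env) { env$orders[[i]]$duration_mult <- 1.0; env }
    }))
  }
  if (!is.null(p$freq_below)) {
    add_flip(env, 3, local({
      i <- idx; b <- p$freq_below
      function(env) { env$orders[[i]]$freq <- b; env }
    }))
  }
  if (!is.null(p$freq_above)) {
    add_flip(env, 3, local({
      i <- idx; b <- p$freq_above
      function(env) { env$orders[[i]]$freq <- b; env }
    }))
  }
  invisible(env)
}

satisfy_atom <- function(p, env, kb, rng) {
  switch(p$kind,
    always = NULL,
    age_in_range = {
      lo <- max(env$age_lo, p$min_days)
      hi <- min(env$age_hi, p$max_days)
      if (lo >= hi) {
        pip_abort("conflicting age constraints", "pip_plan_conflict")
      }
      env$age_lo <- lo; env$age_hi <- hi
      add_flip(env, 6, local({
        mx <- p$max_days
        function(env) { env$age_point <- mx; env }
      }), bound = p$max_days)
    },
    gestational_age_below = {
      env$ga <- p$weeks - 2
      add_flip(env, 4, local({
        w <- p$weeks
        function(env) { env$ga <- w; env }
      }))
    },
    birth_weight_below = {
      env$bw <- p$grams - 300
      add_flip(env, 4, local({
        g <- p$grams
        function(env) { env$bw <- g; env }
      }))
    },
    current_weight_below = {
      env$wt <- p$kg * 0.8
      add_flip(env, 4, local({
        k <- p$kg
        function(env) { env$wt <- k; env }
      }))
    },
    is_premature = { env$ga <- 30 },
    sex_is = { env$sex <- p$sex },
    diagnosis_present = { env$tags <- unique(c(env$tags, p$tag)) },
    procedure_present = {
      env$procedures[[length(env$procedures) + 1L]] <-
        list(tag = p$tag,
             linked = if (!is.null(p$linked_drug))
               resolve_drug_ids(kb$lexicon, p$linked_drug)[1])
    },
    any_medication_present = { env$need_any_med <- TRUE },
    drug_count_at_least = {
      members <- resolve_drug_ids(kb$lexicon, p$drug)
      for (m in members[seq_len(p$n)]) {
        env$orders[[length(env$orders) + 1L]] <- list(
          drug_id = m, route = NULL, dose = NULL, dose_mult = 1.25,
          min_duration = NULL, duration_mult = 1.5, freq = NULL,
          offset_hours = 0, exclusive = TRUE, far_apart = FALSE)
      }
    },
    drug_present = satisfy_drug_atom(p, env, kb, rng),
    co_prescribed = {
      anchor_id <- resolve_drug_ids(kb$lexicon, p$anchor)[1]
      find_or_new_order(env, anchor_id)   # ensure the anchor order exists
      co_id <- pick_member(kb$lexicon, p$drug, rng)
      w <- p$window
      offset <- switch(w$relation,
        within_after = (w$after_hours %||% 0) / 2,
        within_before = -(w$before_hours %||% 0) / 2,
        simultaneous = 0,
        required_gap_before_and_after = 0)
      env$orders[[length(env$orders) + 1L]] <- list(
        drug_id = co_id, route = if (!is.null(p$route)) p$route[[1]],
        dose = NULL, dose_mult = 1.25, min_duration = NULL,
        duration_mult = 1.5, freq = NULL, offset_hours = offset,
        exclusive = TRUE, far_apart = FALSE)
      idx <- length(env$orders)
      clean_offset <- switch(w$relation,
        within_after = (w$after_hours %||% 0) + 1,
        within_before = -((w$before_hours %||% 0) + 1),
        simultaneous = 30 * 24,
        # A month-long separation clears the gap itself and also any
        # sibling branch that pairs the same drugs "simultaneously".
        required_gap_before_and_after = 30 * 24)
      add_flip(env, 5, local({
        i <- idx; off <- clean_offset
        function(env) {
          env$orders[[i]]$offset_hours <- off
          env$orders[[i]]$far_apart <- TRUE
          env
        }
      }))
    },
    pip_abort(paste0("cannot construct atom kind '", p$kind, "'"),
              "pip_plan_error")
  )
  invisible(env)
}

satisfy_pred <- function(p, env, kb, rng) {
  switch(p$kind,
    all_of = { for (ch in p$children) satisfy_pred(ch, env, kb, rng) },
    any_of = {
      k <- length(p$children)
      start <- lcg_int(rng, k)
      done <- FALSE
      chosen <- NA_integer_
      for (j in seq_len(k)) {
        idx <- ((start + j - 1L) %% k) + 1L
        branch <- p$children[[idx]]
        snapshot <- list(age_lo = env$age_lo, age_hi = env$age_hi)
        ok <- tryCatch({ satisfy_pred(branch, env, kb, rng); TRUE },
                       error = function(e) {
                         if (inherits(e, "pip_plan_conflict")) FALSE
                         else stop(e)
                       })
        if (ok) { done <- TRUE; chosen <- idx; break }
        env$age_lo <- snapshot$age_lo; env$age_hi <- snapshot$age_hi
      }
      if (!done) pip_abort("no satisfiable branch", "pip_plan_conflict")
      # Steer the record away from unchosen sibling branches that are bare
      # demographic atoms, so flipping the chosen branch's decisive value
      # cannot leave a sibling satisfied.
      for (idx in setdiff(seq_len(k), chosen)) {
        sib <- p$children[[idx]]
        if (!inherits(sib, "pip_predicate")) next
        if (sib$kind == "age_in_range" && sib$min_days == 0 &&
            sib$max_days < env$age_hi) {
          env$age_lo <- max(env$age_lo, sib$max_days)
        } else if (sib$kind == "current_weight_below" && is.null(env$wt)) {
          env$wt_avoid <- max(env$wt_avoid %||% 0, sib$kg)
        } else if (sib$kind == "birth_weight_below" && is.null(env$bw)) {
          env$bw_avoid <- max(env$bw_avoid %||% 0, sib$grams)
        } else if (sib$kind == "gestational_age_below" && is.null(env$ga)) {
          env$ga_avoid <- max(env$ga_avoid %||% 0, sib$weeks)
        } else if (sib$kind == "not") {
          # A sibling of the form not(X) is satisfied by default (the
          # record starts empty); introduce X so the sibling goes false.
          ch <- sib$child
          if (ch$kind == "procedure_present") {
            env$procedures[[length(env$procedures) + 1L]] <-
              list(tag = ch$tag,
                   linked = if (!is.null(ch$linked_drug))
                     resolve_drug_ids(kb$lexicon, ch$linked_drug)[1])
          } else if (ch$kind == "diagnosis_present") {
            env$tags <- unique(c(env$tags, ch$tag))
          }
        }
      }
    },
    not = NULL,   # defaults never introduce the negated condition
    satisfy_atom(p, env, kb, rng)
  )
  invisible(env)
}

# Pre-scan a trigger for dose/duration constraints per drug so that orders
# created without an active constraint stay safely below every threshold
# that another branch of the same criterion could otherwise reach.
scan_limits <- function(p, kb, limits = new.env(parent = emptyenv())) {
  if (p$kind %in% c("all_of", "any_of")) {
    for (ch in p$children) scan_limits(ch, kb, limits)
  } else if (p$kind == "not") {
    scan_limits(p$child, kb, limits)
  } else if (p$kind == "drug_present") {
    for (d in resolve_drug_ids(kb$lexicon, p$drug)) {
      cur <- limits[[d]] %||% list()
      if (!is.null(p$dose)) cur$dose <- c(cur$dose, list(p$dose))
      if (!is.null(p$min_duration))
        cur$duration <- c(cur$duration, list(p$min_duration))
      if (!is.null(p$freq_above))
        cur$freq_above <- min(cur$freq_above %||% Inf, p$freq_above)
      limits[[d]] <- cur
    }
  }
  limits
}

materialize_record <- function(env, criterion, kb, record_id, rng,
                               limits = NULL) {
  age <- env$age_point %||% (env$age_lo + (env$age_hi - 1 - env$age_lo) %/% 2)
  wt <- env$wt %||% max(default_weight_kg(age), env$wt_avoid %||% 0)
  sex <- env$sex %||% c("male", "female")[lcg_int(rng, 2) + 1L]
  ga <- env$ga %||% max(39, env$ga_avoid %||% 0)
  bw <- env$bw %||% max(if (ga < 37) 2000 else 3300, env$bw_avoid %||% 0)
  enc_date <- as.Date("2024-03-01")
  t0 <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")

  orders <- list()
  for (i in seq_along(env$orders)) {
    s <- env$orders[[i]]
    freq <- s$freq %||% 1L
    dur <- 5
    if (!is.null(s$min_duration)) {
      dur <- duration_to_days(s$min_duration$value, s$min_duration$unit) *
        s$duration_mult
      if (s$duration_mult > 1) dur <- max(dur, 1 / 24)
    }
    # derive the daily amount from the dose constraint (or a safe default)
    lim <- if (!is.null(limits)) limits[[s$drug_id]] else NULL
    mg_day <- 0.08 * wt * 24  # bland default ~2 mg/kg/d
    cumulative <- NULL
    if (!is.null(s$dose)) {
      d <- s$dose
      thr <- mass_to_mg(d$threshold, d$unit) * s$dose_mult
      mg_day <- switch(d$metric,
        per_kg_per_day = thr * wt,
        per_day = thr,
        per_dose = thr * freq,
        per_kg_per_hour = thr * wt * 24,
        cumulative_total = { cumulative <- thr; 2 * wt },
        cumulative_per_kg = { cumulative <- thr * wt; 2 * wt })
    } else if (!is.null(lim) && length(lim$dose)) {
      # stay at half of the tightest threshold any sibling clause names
      caps <- vapply(lim$dose, function(d) {
        thr <- mass_to_mg(d$threshold, d$unit)
        switch(d$metric,
          per_kg_per_day = thr * wt, per_day = thr, per_dose = thr * freq,
          per_kg_per_hour = thr * wt * 24,
          cumulative_total = Inf, cumulative_per_kg = Inf)
      }, numeric(1))
      mg_day <- min(mg_day, 0.5 * min(caps))
      cum_caps <- vapply(lim$dose, function(d) {
        thr <- mass_to_mg(d$threshold, d$unit)
        switch(d$metric, cumulative_total = thr,
               cumulative_per_kg = thr * wt, Inf)
      }, numeric(1))
      if (any(is.finite(cum_caps))) cumulative <- 0.5 * min(cum_caps)
    }
    if (!is.null(lim) && length(lim$duration) && is.null(s$min_duration)) {
      dmin <- min(vapply(lim$duration, function(x)
        duration_to_days(x$value, x$unit), numeric(1)))
      dur <- min(dur, 0.5 * dmin)
    }
    if (!is.null(lim) && is.finite(lim$freq_above %||% Inf) &&
        is.null(s$freq)) {
      freq <- min(freq, lim$freq_above)
    }
    dose_amount <- round(mg_day / freq, 4)
    orders[[i]] <- medication_order(
      order_id = sprintf("%s-o%d", record_id, i),
      drug_text = drug_label(kb$lexicon, s$drug_id), drug_id = s$drug_id,
      dose_amount = dose_amount, dose_unit = "mg",
      frequency_per_day = freq,
      route = s$route %||% default_route(kb$lexicon, s$drug_id),
      start_time = t0 + s$offset_hours * 3600,
      duration_days = if (isTRUE(s$far_apart)) 1 else round(dur, 3),
      cumulative_dose = cumulative, cumulative_unit = "mg")
  }
  if (isTRUE(env$need_any_med) && !length(orders)) {
    orders[[1]] <- medication_order(
      order_id = paste0(record_id, "-o1"), drug_text = "Vitamin D",
      drug_id = "vitamin_d", dose_amount = 0.01, dose_unit = "mg",
      frequency_per_day = 1L, route = "oral", start_time = t0,
      duration_days = 30)
  }
  procedures <- lapply(env$procedures, function(pr)
    procedure_order(procedure_tag = pr$tag, linked_drug_id = pr$linked,
                    time = t0))
  patient <- patient_profile(
    patient_id = paste0("pt-", record_id), sex = sex,
    age_days_at_encounter = as.integer(age),
    gestational_age_weeks = ga, birth_weight_g = bw,
    current_weight_kg = wt, diagnosis_tags = sort(env$tags),
    clinical_flags = character())
  prescription_record(record_id = record_id, encounter_date = enc_date,
                      patient = patient, orders = orders,
                      procedures = procedures)
}

drug_label <- function(lexicon, drug_id) {
  for (d in lexicon$drugs) if (d$canonical_id == drug_id) return(d$label)
  drug_id
}

default_route <- function(lexicon, drug_id) "oral"

plan_criterion <- function(criterion, kb, rng) {
  env <- new_plan_env()
  satisfy_pred(criterion$trigger, env, kb, rng)
  env
}

#' Construct a record that violates a criterion
#'
#' Builds a minimal prescription record satisfying the criterion's
#' trigger, with its exception definitely unsatisfied and, for a PPO
#' criterion, the required action absent. Demographics not pinned by the
#' trigger take defaults (gestational age 39 weeks, birth weight
#' appropriate, weight from a reference weight-for-age), so exception
#' clauses about prematurity or comorbidity are definitely false rather
#' than indeterminate.
#'
#' @param criterion A [criterion()] from the knowledge base.
#' @param kb The `pip_kb` it belongs to.
#' @param seed Integer seed; construction is deterministic per seed.
#' @param record_id Record id to assign.
#' @return A [prescription_record()].
#' @export
plant_positive <- function(criterion, kb, seed = 1,
                           record_id = paste0("pos-", criterion$criterion_id)) {
  rng <- lcg_new(seed * 131 + criterion_hash(criterion$criterion_id))
  env <- plan_criterion(criterion, kb, rng)
  limits <- scan_limits(criterion$trigger, kb)
  materialize_record(env, criterion, kb, record_id, rng, limits)
}

criterion_hash <- function(id) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 10007
}

#' Construct a near-miss record on the clean side of a threshold
#'
#' Same construction as [plant_positive()] except that the decisive
#' numeric quantity of the satisfied trigger path is placed on the
#' non-flagging side of its threshold, respecting the printed strictness:
#' a dose sits exactly at a strict `>` cutoff, an age at the first day
#' past an exclusive bound, a co-prescription one hour outside its
#' window. Flip preference order: dose, duration, frequency,
#' weight/gestational-age/birth-weight bounds, temporal windows, then age
#' ranges (narrowest first).
#'
#' @inheritParams plant_positive
#' @return A [prescription_record()] expected NOT to flag the criterion.
#' @export
plant_boundary_negative <- function(criterion, kb, seed = 1,
                                    record_id = paste0("neg-", criterion$criterion_id)) {
  rng <- lcg_new(seed * 131 + criterion_hash(criterion$criterion_id))
  env <- plan_criterion(criterion, kb, rng)
  if (!length(env$flips)) {
    pip_abort(paste0(criterion$criterion_id,
                     ": no numeric threshold to place a boundary on"),
              "pip_plan_error")
  }
  prio <- vapply(env$flips, `[[`, numeric(1), "priority")
  pick <- if (all(prio == 6)) {
    # among age ranges prefer the narrowest explicit bound
    bounds <- vapply(env$flips, `[[`, numeric(1), "bound")
    which.min(bounds)
  } else {
    which.min(prio)
  }
  env <- env$flips[[pick]]$apply(env)
  limits <- scan_limits(criterion$trigger, kb)
  materialize_record(env, criterion, kb, record_id, rng, limits)
}

#' Cohort generation configuration
#'
#' @param n_records Total records in the cohort (planted + background).
#' @param seed Integer seed.
#' @param strata_weights Named numeric weights for the background age
#'   strata `premature_neonate`, `term_neonate`, `infant`, `child`,
#'   `adolescent`.
#' @param background_drugs Canonical ids of benign drugs background
#'   records draw from.
#' @param plan `data.frame(criterion_id, count_positives,
#'   count_boundary_negatives)`; `NULL` for no planted records.
#' @return A `pip_cohort_config`.
#' @export
cohort_config <- function(n_records, seed = 1,
                          strata_weights = c(premature_neonate = 0.05,
                                             term_neonate = 0.1,
                                             infant = 0.25, child = 0.4,
                                             adolescent = 0.2),
                          background_drugs = c("vitamin_d", "simethicone",
                                               "lactulose",
                                               "saline_nasal_spray"),
                          plan = NULL) {
  if (any(strata_weights < 0) || sum(strata_weights) <= 0) {
    pip_abort("stratum weights must be nonnegative with positive sum",
              "pip_config_error")
  }
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 strata_weights = strata_weights,
                 background_drugs = background_drugs, plan = plan),
            class = "pip_cohort_config")
}

#' A violation plan covering every criterion
#'
#' @param kb A `pip_kb`.
#' @param positives,negatives Plants per criterion.
#' @return `data.frame` plan for [cohort_config()].
#' @export
full_sweep_plan <- function(kb, positives = 1, negatives = 1) {
  data.frame(
    criterion_id = vapply(kb$criteria, `[[`, character(1), "criterion_id"),
    count_positives = positives, count_boundary_negatives = negatives,
    stringsAsFactors = FALSE)
}

sample_stratum_age <- function(stratum, rng) {
  switch(stratum,
    premature_neonate = lcg_int(rng, 29),
    term_neonate = lcg_int(rng, 29),
    infant = 29L + lcg_int(rng, years_to_days(2) - 29L),
    child = years_to_days(2) + lcg_int(rng, years_to_days(12) - years_to_days(2)),
    adolescent = years_to_days(12) + lcg_int(rng, years_to_days(18) - years_to_days(12)))
}

background_record <- function(i, config, kb, rng) {
  strata <- names(config$strata_weights)
  w <- cumsum(config$strata_weights) / sum(config$strata_weights)
  stratum <- strata[findInterval(lcg_unif(rng), w) + 1L]
  age <- sample_stratum_age(stratum, rng)
  ga <- if (stratum == "premature_neonate") 28 + lcg_int(rng, 9) else
    37 + lcg_int(rng, 5)
  wt <- default_weight_kg(age)
  record_id <- sprintf("bg-%04d", i)
  n_orders <- lcg_int(rng, 4)
  t0 <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
  orders <- lapply(seq_len(n_orders), function(j) {
    drug <- config$background_drugs[lcg_int(rng, length(config$background_drugs)) + 1L]
    medication_order(
      order_id = sprintf("%s-o%d", record_id, j),
      drug_text = drug_label(kb$lexicon, drug), drug_id = drug,
      dose_amount = round(1 + lcg_unif(rng) * 50, 1), dose_unit = "mg",
      frequency_per_day = 1L + lcg_int(rng, 3), route = "oral",
      start_time = if (lcg_unif(rng) < 0.7) t0 + lcg_int(rng, 72) * 3600,
      duration_days = if (lcg_unif(rng) < 0.8) 1 + lcg_int(rng, 10))
  })
  patient <- patient_profile(
    patient_id = paste0("pt-", record_id),
    sex = c("male", "female")[lcg_int(rng, 2) + 1L],
    age_days_at_encounter = age, gestational_age_weeks = ga,
    birth_weight_g = if (ga < 37) 1600 + lcg_int(rng, 1200) else
      2800 + lcg_int(rng, 1400),
    current_weight_kg = if (lcg_unif(rng) < 0.9) wt,
    diagnosis_tags = character(), clinical_flags = character())
  prescription_record(record_id = record_id, encounter_date = as.Date("2024-03-01"),
                      patient = patient, orders = orders, procedures = list())
}

#' Generate a cohort with planted violations and ground-truth labels
#'
#' @param config A [cohort_config()].
#' @param kb A `pip_kb`.
#' @return `list(records, labels)`: the records and a
#'   `data.frame(record_id, criterion_id, expectation)` with expectation
#'   `"flag"` for planted positives and `"clean"` for boundary negatives.
#' @export
generate_cohort <- function(config, kb) {
  plan <- config$plan
  crit_by_id <- stats::setNames(kb$criteria,
                                vapply(kb$criteria, `[[`, character(1),
                                       "criterion_id"))
  records <- list()
  labels <- list()
  n_planted <- 0L
  if (!is.null(plan) && nrow(plan)) {
    bad <- setdiff(plan$criterion_id, names(crit_by_id))
    if (length(bad)) {
      pip_abort(paste0("plan references unknown criteria: ",
                       paste(bad, collapse = ", ")), "pip_config_error")
    }
    n_planted <- sum(plan$count_positives) + sum(plan$count_boundary_negatives)
    if (n_planted > config$n_records) {
      pip_abort("violation plan exceeds the record budget", "pip_config_error")
    }
    for (i in seq_len(nrow(plan))) {
      cr <- crit_by_id[[plan$criterion_id[i]]]
      for (k in seq_len(plan$count_positives[i])) {
        rid <- sprintf("pos-%s-%d", cr$criterion_id, k)
        records[[length(records) + 1L]] <-
          plant_positive(cr, kb, seed = config$seed + k, record_id = rid)
        labels[[length(labels) + 1L]] <- data.frame(
          record_id = rid, criterion_id = cr$criterion_id,
          expectation = "flag", stringsAsFactors = FALSE)
      }
      for (k in seq_len(plan$count_boundary_negatives[i])) {
        rid <- sprintf("neg-%s-%d", cr$criterion_id, k)
        records[[length(records) + 1L]] <-
          plant_boundary_negative(cr, kb, seed = config$seed + k,
                                  record_id = rid)
        labels[[length(labels) + 1L]] <- data.frame(
          record_id = rid, criterion_id = cr$criterion_id,
          expectation = "clean", stringsAsFactors = FALSE)
      }
    }
  }
  rng <- lcg_new(config$seed)
  n_background <- config$n_records - n_planted
  for (i in seq_len(n_background)) {
    for (attempt in 1:10) {
      rec <- background_record(i, config, kb, rng)
      if (nrow(screen_record(rec, kb)$flags) == 0L) break
      if (attempt == 10)
        pip_abort("could not draw a non-triggering background record",
                  "pip_config_error")
    }
    records[[length(records) + 1L]] <- rec
  }
  labels_df <- if (length(labels)) do.call(rbind, labels) else
    data.frame(record_id = character(), criterion_id = character(),
               expectation = character(), stringsAsFactors = FALSE)
  list(records = records, labels = labels_df)
}

#' Write a generated cohort and its label file
#'
#' Emits the `patients.csv` / `orders.csv` / `procedures.csv` trio plus
#' `labels.csv` (`record_id`, `criterion_id`, `expectation`).
#'
#' @param cohort Result of [generate_cohort()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_prescriptions(cohort$records, path)
  utils::write.csv(cohort$labels, file.path(path, "labels.csv"),
                   row.names = FALSE)
  invisible(path)
}
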