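#' Screening engine: three-valued criterion evaluation
#'
#' Criteria are evaluated against a record under strong-Kleene three-valued
#' logic. An atom whose inputs are missing from the record (weight for a
#' per-kg dose, a timestamp for a temporal window, gestational age for
#' prematurity) is `indeterminate` and names the missing field; `all_of` is
#' `not_satisfied` as soon as one child is, `satisfied` when all are, and
#' `indeterminate` otherwise; `any_of` dually; `not` swaps the definite
#' outcomes and preserves `indeterminate`. A criterion whose decisive
#' input is indeterminate is reported as unscreenable rather than silently
#' passed: filling in a missing field can only resolve indeterminate
#' outcomes, never flip a definite one.
#'
#' @name screening
#' @keywords internal
NULL

out_sat <- function(matched = character()) {
  list(status = "satisfied", missing_inputs = character(),
       matched_orders = matched)
}
out_not <- function() {
  list(status = "not_satisfied", missing_inputs = character(),
       matched_orders = character())
}
out_ind <- function(missing) {
  list(status = "indeterminate", missing_inputs = unique(missing),
       matched_orders = character())
}

combine_all_of <- function(outs) {
  statuses <- vapply(outs, `[[`, character(1), "status")
  if (any(statuses == "not_satisfied")) return(out_not())
  if (any(statuses == "indeterminate")) {
    return(out_ind(unlist(lapply(outs, `[[`, "missing_inputs"))))
  }
  out_sat(sort(unique(unlist(lapply(outs, `[[`, "matched_orders")))))
}

combine_any_of <- function(outs) {
  statuses <- vapply(outs, `[[`, character(1), "status")
  if (any(statuses == "satisfied")) {
    sat <- outs[statuses == "satisfied"]
    return(out_sat(sort(unique(unlist(lapply(sat, `[[`, "matched_orders"))))))
  }
  if (any(statuses == "indeterminate")) {
    return(out_ind(unlist(lapply(outs, `[[`, "missing_inputs"))))
  }
  out_not()
}

negate_outcome <- function(o) {
  switch(o$status,
    satisfied = out_not(),
    not_satisfied = out_sat(),
    o
  )
}

# Precompute the derived quantities predicates consume.
record_context <- function(record, kb) {
  age <- derive_age_profile(record$patient, record$encounter_date)
  orders <- lapply(record$orders, function(o) {
    if (is.na(o$drug_id %||% NA_character_) && !is.null(o$drug_text)) {
      o$drug_id <- canonicalize_drug(o$drug_text, kb$lexicon)
    }
    o$dose_profile <- derive_dose_profile(o, record$patient)
    o
  })
  list(record = record, patient = record$patient, age = age, orders = orders,
       tags = unique(c(record$patient$diagnosis_tags,
                       record$patient$clinical_flags)),
       procedures = record$procedures)
}

#' Evaluate the timing of a co-prescribed pair against a temporal window
#'
#' Determines whether the relative timing of an index order `a` and a
#' co-prescribed order `b` constitutes the interaction described by
#' `window` (see [temporal_window()] for the relation semantics). When
#' both orders lack timestamps they are treated as simultaneous; when
#' exactly one timestamp is missing the outcome is indeterminate.
#'
#' @param a Index (anchor) [medication_order()].
#' @param b Co-prescribed [medication_order()].
#' @param window A [temporal_window()].
#' @return An evaluation outcome: `list(status, missing_inputs, ...)` with
#'   status `"satisfied"` (the window is violated), `"not_satisfied"`, or
#'   `"indeterminate"`.
#' @export
within_window <- function(a, b, window) {
  ta <- a$start_time
  tb <- b$start_time
  if (is.null(ta) && is.null(tb)) {
    # same record, no timing information: treat as simultaneous
    delta <- 0
    overlap <- TRUE
  } else if (is.null(ta) || is.null(tb)) {
    return(out_ind("start_time"))
  } else {
    delta <- as.numeric(difftime(ta, tb, units = "hours"))
    dur_a <- (a$duration_days %||% 1) * 24
    dur_b <- (b$duration_days %||% 1) * 24
    overlap <- (delta <= dur_b) && (-delta <= dur_a)
  }
  hit <- switch(window$relation,
    within_after = (-delta >= 0) && (-delta <= window$after_hours),
    within_before = (delta >= 0) && (delta <= window$before_hours),
    simultaneous = overlap,
    required_gap_before_and_after =
      (delta > -window$before_hours) && (delta < window$after_hours),
    stop("unknown window relation: ", window$relation)
  )
  if (hit) out_sat(sort(c(a$order_id, b$order_id))) else out_not()
}

# Match one order against a drug_present atom. Returns "yes", "no" or a
# character vector of missing inputs ("maybe").
match_order_atom <- function(order, p, members) {
  if (is.na(order$drug_id %||% NA_character_) ||
      !(order$drug_id %in% members)) {
    return("no")
  }
  missing <- character()
  if (!is.null(p$route)) {
    if (is.null(order$route)) {
      missing <- c(missing, "route")
    } else if (!order$route %in% p$route) {
      return("no")
    }
  }
  if (!is.null(p$dose)) {
    d <- p$dose
    prof <- order$dose_profile
    value <- switch(d$metric,
      per_kg_per_day = prof$mg_per_kg_per_day,
      per_day = prof$mg_per_day,
      per_dose = prof$mg_per_dose,
      per_kg_per_hour = prof$mg_per_kg_per_hour,
      cumulative_total = prof$cumulative_mg,
      cumulative_per_kg = prof$cumulative_mg_per_kg
    )
    if (is.na(value)) {
      missing <- c(missing, prof$missing_inputs)
    } else {
      thr <- mass_to_mg(d$threshold, d$unit)
      hit <- if (isTRUE(d$inclusive)) value >= thr else value > thr
      if (!hit) return("no")
    }
  }
  if (!is.null(p$min_duration)) {
    if (is.null(order$duration_days)) {
      missing <- c(missing, "duration_days")
    } else {
      thr_days <- duration_to_days(p$min_duration$value, p$min_duration$unit)
      if (!(order$duration_days > thr_days)) return("no")
    }
  }
  if (!is.null(p$freq_below) || !is.null(p$freq_above)) {
    if (is.null(order$frequency_per_day)) {
      missing <- c(missing, "frequency_per_day")
    } else {
      f <- order$frequency_per_day
      if (!is.null(p$freq_below) && !(f < p$freq_below)) return("no")
      if (!is.null(p$freq_above) && !(f > p$freq_above)) return("no")
    }
  }
  if (length(missing)) missing else "yes"
}

existential_over <- function(results, ids) {
  yes <- vapply(results, identical, logical(1), "yes")
  if (any(yes)) return(out_sat(sort(unique(ids[yes]))))
  maybe <- !yes & !vapply(results, identical, logical(1), "no")
  if (any(maybe)) return(out_ind(unlist(results[maybe])))
  out_not()
}

eval_atom <- function(p, ctx, kb) {
  switch(p$kind,
    always = out_sat(),
    age_in_range = {
      d <- ctx$age$postnatal_days
      if (d >= p$min_days && d < p$max_days) out_sat() else out_not()
    },
    gestational_age_below = {
      ga <- ctx$patient$gestational_age_weeks
      if (is.null(ga)) out_ind("gestational_age_weeks")
      else if (ga < p$weeks) out_sat() else out_not()
    },
    birth_weight_below = {
      bw <- ctx$patient$birth_weight_g
      if (is.null(bw)) out_ind("birth_weight_g")
      else if (bw < p$grams) out_sat() else out_not()
    },
    current_weight_below = {
      wt <- ctx$patient$current_weight_kg
      if (is.null(wt)) out_ind("current_weight_kg")
      else if (wt < p$kg) out_sat() else out_not()
    },
    is_premature = {
      prem <- ctx$age$is_premature
      if (is.na(prem)) out_ind("gestational_age_weeks")
      else if (prem) out_sat() else out_not()
    },
    sex_is = {
      if (ctx$patient$sex == "unknown") out_ind("sex")
      else if (ctx$patient$sex == p$sex) out_sat() else out_not()
    },
    diagnosis_present = {
      if (p$tag %in% ctx$tags) out_sat() else out_not()
    },
    any_medication_present = {
      if (length(ctx$orders) > 0L) {
        out_sat(sort(vapply(ctx$orders, `[[`, character(1), "order_id")))
      } else out_not()
    },
    drug_count_at_least = {
      members <- resolve_drug_ids(kb$lexicon, p$drug)
      present <- unique(stats::na.omit(vapply(ctx$orders, function(o)
        o$drug_id %||% NA_character_, character(1))))
      hits <- intersect(present, members)
      if (length(hits) >= p$n) {
        ids <- vapply(ctx$orders, `[[`, character(1), "order_id")
        m <- vapply(ctx$orders, function(o)
          (o$drug_id %||% NA_character_) %in% hits, logical(1))
        out_sat(sort(ids[m]))
      } else out_not()
    },
    drug_present = {
      members <- resolve_drug_ids(kb$lexicon, p$drug)
      res <- lapply(ctx$orders, match_order_atom, p = p, members = members)
      ids <- vapply(ctx$orders, `[[`, character(1), "order_id")
      existential_over(res, ids)
    },
    co_prescribed = {
      anchor_members <- resolve_drug_ids(kb$lexicon, p$anchor)
      co_members <- resolve_drug_ids(kb$lexicon, p$drug)
      drug_of <- function(o) o$drug_id %||% NA_character_
      anchors <- Filter(function(o) !is.na(drug_of(o)) &&
                          drug_of(o) %in% anchor_members, ctx$orders)
      cos <- Filter(function(o) {
        if (is.na(drug_of(o)) || !drug_of(o) %in% co_members) return(FALSE)
        is.null(p$route) || (!is.null(o$route) && o$route %in% p$route)
      }, ctx$orders)
      # a route-constrained co-order with no recorded route is a "maybe"
      cos_maybe <- if (!is.null(p$route)) {
        Filter(function(o) !is.na(drug_of(o)) && drug_of(o) %in% co_members &&
                 is.null(o$route), ctx$orders)
      } else list()
      outs <- list()
      for (a in anchors) {
        for (b in c(cos, cos_maybe)) {
          if (identical(a$order_id, b$order_id)) next
          o <- within_window(a, b, p$window)
          if (o$status == "satisfied" &&
              any(vapply(cos_maybe, function(x)
                identical(x$order_id, b$order_id), logical(1)))) {
            o <- out_ind("route")
          }
          outs[[length(outs) + 1L]] <- o
        }
      }
      if (!length(outs)) return(out_not())
      combine_any_of(outs)
    },
    procedure_present = {
      if (!length(ctx$procedures)) return(out_not())
      cand <- Filter(function(pr) identical(pr$procedure_tag, p$tag),
                     ctx$procedures)
      if (!length(cand)) return(out_not())
      if (is.null(p$linked_drug)) return(out_sat())
      members <- resolve_drug_ids(kb$lexicon, p$linked_drug)
      res <- vapply(cand, function(pr) {
        ld <- pr$linked_drug_id
        if (is.null(ld)) return("maybe")
        if (ld %in% members || identical(ld, p$linked_drug)) "yes" else "no"
      }, character(1))
      if (any(res == "yes")) out_sat()
      else if (any(res == "maybe")) out_ind("linked_drug_id")
      else out_not()
    },
    stop("unknown predicate kind: ", p$kind)
  )
}

eval_pred <- function(p, ctx, kb) {
  switch(p$kind,
    all_of = combine_all_of(lapply(p$children, eval_pred, ctx = ctx, kb = kb)),
    any_of = combine_any_of(lapply(p$children, eval_pred, ctx = ctx, kb = kb)),
    not = negate_outcome(eval_pred(p$child, ctx, kb)),
    eval_atom(p, ctx, kb)
  )
}

#' Evaluate a predicate against a prescription record
#'
#' @param p A [predicate][predicate-constructors] validated against the
#'   knowledge base's lexicon and vocabulary.
#' @param record A [prescription_record()].
#' @param kb The `pip_kb` supplying the lexicon/vocabulary.
#' @return `list(status, missing_inputs, matched_orders)` with status one
#'   of `"satisfied"`, `"not_satisfied"`, `"indeterminate"`.
#' @export
evaluate_predicate <- function(p, record, kb) {
  ctx <- record_context(record, kb)
  eval_pred(p, ctx, kb)
}

SEVERITY_RANK <- c(caution = 1, avoid = 2)

empty_flags_df <- function() {
  data.frame(record_id = character(), criterion_id = character(),
             category = character(), severity = character(),
             matched_orders = character(), rationale = character(),
             stringsAsFactors = FALSE)
}

evaluate_criterion <- function(cr, ctx, kb) {
  trig <- eval_pred(cr$trigger, ctx, kb)
  if (trig$status == "not_satisfied") {
    return(list(outcome = "clear"))
  }
  exc <- if (is.null(cr$exception)) out_not() else eval_pred(cr$exception, ctx, kb)
  if (trig$status == "indeterminate" ||
      (trig$status == "satisfied" && exc$status == "indeterminate")) {
    return(list(outcome = "indeterminate",
                missing = unique(c(trig$missing_inputs, exc$missing_inputs))))
  }
  if (exc$status == "satisfied") {
    return(list(outcome = "clear"))
  }
  # trigger satisfied, exception definitely not
  if (cr$category == "PIM") {
    clause_outs <- lapply(cr$severity_clauses, function(sc)
      eval_pred(sc$predicate, ctx, kb))
    stat <- vapply(clause_outs, `[[`, character(1), "status")
    if (any(stat == "satisfied")) {
      sev <- vapply(cr$severity_clauses[stat == "satisfied"], `[[`,
                    character(1), "severity")
      sev <- names(which.max(SEVERITY_RANK[unique(sev)]))
      matched <- sort(unique(c(trig$matched_orders,
        unlist(lapply(clause_outs[stat == "satisfied"], `[[`,
                      "matched_orders")))))
      return(list(outcome = "flag", severity = sev, matched = matched))
    }
    if (any(stat == "indeterminate")) {
      return(list(outcome = "indeterminate",
                  missing = unique(unlist(lapply(clause_outs, `[[`,
                                                 "missing_inputs")))))
    }
    return(list(outcome = "clear"))
  }
  # PPO: flag when the required action is definitely absent
  req <- eval_pred(cr$required_action, ctx, kb)
  switch(req$status,
    not_satisfied = list(outcome = "flag", severity = "omission",
                         matched = trig$matched_orders),
    satisfied = list(outcome = "clear"),
    list(outcome = "indeterminate", missing = req$missing_inputs)
  )
}

#' Screen one prescription record against a knowledge base
#'
#' Evaluates every criterion. A PIM criterion flags when its trigger is
#' satisfied, its exception is definitely not satisfied and at least one
#' severity clause is satisfied; the reported severity is the maximum
#' (`avoid` > `caution`) over satisfied clauses. A PPO criterion flags when
#' trigger holds, the exception does not, and the required action is
#' definitely absent. Criteria whose decisive input is indeterminate are
#' listed in `indeterminate` with the missing field names. Output ordering
#' is deterministic (by criterion id).
#'
#' @param record A [prescription_record()].
#' @param kb A validated `pip_kb`.
#' @return A `pip_screening_result`: `record_id`, `flags` (`data.frame`
#'   with `record_id`, `criterion_id`, `category`, `severity`,
#'   `matched_orders` (";"-joined), `rationale`) and `indeterminate`
#'   (`data.frame` with `criterion_id`, `missing_inputs`).
#' @export
screen_record <- function(record, kb) {
  ctx <- record_context(record, kb)
  flags <- list()
  indet <- list()
  for (cr in kb$criteria) {
    res <- evaluate_criterion(cr, ctx, kb)
    if (res$outcome == "flag") {
      flags[[length(flags) + 1L]] <- data.frame(
        record_id = record$record_id, criterion_id = cr$criterion_id,
        category = cr$category, severity = res$severity,
        matched_orders = paste(res$matched, collapse = ";"),
        rationale = cr$risk_text, stringsAsFactors = FALSE)
    } else if (res$outcome == "indeterminate") {
      indet[[length(indet) + 1L]] <- data.frame(
        criterion_id = cr$criterion_id,
        missing_inputs = paste(sort(res$missing), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    record_id = record$record_id,
    flags = if (length(flags)) do.call(rbind, flags) else empty_flags_df(),
    indeterminate = if (length(indet)) do.call(rbind, indet) else
      data.frame(criterion_id = character(), missing_inputs = character(),
                 stringsAsFactors = FALSE)
  ), class = "pip_screening_result")
}

#' Screen a cohort of prescription records
#'
#' @param records List of [prescription_record()]s with unique record ids.
#' @param kb A validated `pip_kb`.
#' @return A `pip_cohort_screening`: `results` (list of per-record
#'   [screen_record()] results), `flags` (row-bound flag table) and
#'   `summary` with `n_records`, `n_flagged` (records with >= 1 flag),
#'   `prevalence` (`NA` for an empty cohort), `n_pim_flags`, `n_ppo_flags`,
#'   per-criterion hit counts (`hits_by_criterion`: records flagged per
#'   criterion) and per-criterion indeterminate record counts.
#' @export
screen_cohort <- function(records, kb) {
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    pip_abort(paste0("duplicate record_id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "pip_input_error")
  }
  results <- lapply(records, screen_record, kb = kb)
  flags <- do.call(rbind, c(list(empty_flags_df()),
                            lapply(results, `[[`, "flags")))
  indet <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$indeterminate)) {
      cbind(record_id = r$record_id, r$indeterminate,
            stringsAsFactors = FALSE)
    } else NULL
  }))
  hit_tab <- if (nrow(flags)) {
    as.data.frame(table(criterion_id = flags$criterion_id),
                  responseName = "n_records", stringsAsFactors = FALSE)
  } else {
    data.frame(criterion_id = character(), n_records = integer(),
               stringsAsFactors = FALSE)
  }
  indet_tab <- if (!is.null(indet) && nrow(indet)) {
    as.data.frame(table(criterion_id = indet$criterion_id),
                  responseName = "n_records", stringsAsFactors = FALSE)
  } else {
    data.frame(criterion_id = character(), n_records = integer(),
               stringsAsFactors = FALSE)
  }
  n <- length(records)
  n_flagged <- sum(vapply(results, function(r) nrow(r$flags) > 0, logical(1)))
  summary <- list(
    n_records = n, n_flagged = n_flagged,
    prevalence = if (n > 0) n_flagged / n else NA_real_,
    n_pim_flags = sum(flags$category == "PIM"),
    n_ppo_flags = sum(flags$category == "PPO"),
    n_indeterminate = if (is.null(indet)) 0L else nrow(indet),
    hits_by_criterion = hit_tab,
    indeterminate_by_criterion = indet_tab
  )
  structure(list(results = results, flags = flags, summary = summary),
            class = "pip_cohort_screening")
}

#' @export
print.pip_cohort_screening <- function(x, ...) {
  s <- x$summary
  cat("Screened", s$n_records, "records:", s$n_flagged, "with >=1 flag",
      sprintf("(prevalence %s)",
              ifelse(is.na(s$prevalence), "n/a",
                     sprintf("%.1f%%", 100 * s$prevalence))), "\n")
  cat("Flags:", s$n_pim_flags, "PIM,", s$n_ppo_flags, "PPO;",
      s$n_indeterminate, "indeterminate criterion evaluations\n")
  invisible(x)
}
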