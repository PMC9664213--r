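#' Predicate expression language for prescribing criteria
#'
#' Each screening criterion is driven by a small expression tree built from
#' atoms about the patient (age, weight, sex, gestational age), the
#' medication orders (drug identity, route, dose rate, duration, frequency,
#' co-prescription timing) and the clinical context (diagnosis tags,
#' procedure orders), combined with `all_of` / `any_of` / `not`.
#'
#' Atoms that quantify over medication orders are existential: the atom is
#' satisfied when at least one order matches every constraint it carries.
#' Dose, duration and frequency conditions are expressed as optional
#' constraint fields of [pred_drug_present()] so that conjunctive
#' conditions such as "more than 4 mg/kg/h for more than 48 h" apply to a
#' single order rather than to two different orders of the same drug.
#'
#' @name predicates
#' @keywords internal
NULL

new_predicate <- function(kind, fields = list()) {
  # Absent optional fields are dropped (not kept as explicit NULLs) so a
  # constructed predicate is identical to its serialized round trip.
  fields <- fields[!vapply(fields, is.null, logical(1))]
  structure(c(list(kind = kind), fields), class = "pip_predicate")
}

#' @rdname predicate-constructors
#' @export
pred_all_of <- function(...) new_predicate("all_of", list(children = unname(list(...))))

#' @rdname predicate-constructors
#' @export
pred_any_of <- function(...) new_predicate("any_of", list(children = unname(list(...))))

#' @rdname predicate-constructors
#' @export
pred_not <- function(child) new_predicate("not", list(child = child))

#' @rdname predicate-constructors
#' @export
pred_always <- function() new_predicate("always")

#' Predicate constructors
#'
#' Build atoms of the criterion predicate language. Ages are whole
#' postnatal days with `min_days` inclusive and `max_days` exclusive.
#'
#' @param min_days,max_days Half-open postnatal-day interval.
#' @param weeks Gestational age bound in completed weeks (strict `<`).
#' @param grams Birth-weight bound in grams (strict `<`).
#' @param kg Current-weight bound in kilograms (strict `<`).
#' @param sex One of `"male"`, `"female"`.
#' @param drug Canonical drug or drug-class identifier from the lexicon.
#' @param route Optional character vector of acceptable routes.
#' @param dose Optional dose constraint from [dose_exceeds()].
#' @param min_duration Optional duration constraint from [duration_exceeds()].
#' @param freq_below,freq_above Optional integer bounds on doses per day:
#'   the order matches when `frequency < freq_below` or
#'   `frequency > freq_above` respectively.
#' @param anchor Canonical id of the index drug of a co-prescription pair.
#' @param window Temporal window from [temporal_window()].
#' @param tag Condition-vocabulary tag id.
#' @param linked_drug Optional drug/class id a procedure must refer to.
#' @param n Minimum number of distinct drugs.
#' @param child A predicate to negate.
#' @param ... Child predicates.
#' @return A `pip_predicate` object.
#' @name predicate-constructors
NULL

#' @rdname predicate-constructors
#' @export
pred_age_in_range <- function(min_days, max_days) {
  stopifnot(min_days >= 0, max_days > min_days)
  new_predicate("age_in_range", list(min_days = as.integer(min_days),
                                     max_days = as.integer(max_days)))
}

#' @rdname predicate-constructors
#' @export
pred_gestational_age_below <- function(weeks) {
  new_predicate("gestational_age_below", list(weeks = as.numeric(weeks)))
}

#' @rdname predicate-constructors
#' @export
pred_birth_weight_below <- function(grams) {
  new_predicate("birth_weight_below", list(grams = as.numeric(grams)))
}

#' @rdname predicate-constructors
#' @export
pred_current_weight_below <- function(kg) {
  new_predicate("current_weight_below", list(kg = as.numeric(kg)))
}

#' @rdname predicate-constructors
#' @export
pred_is_premature <- function() new_predicate("is_premature")

#' @rdname predicate-constructors
#' @export
pred_sex_is <- function(sex) {
  stopifnot(sex %in% c("male", "female"))
  new_predicate("sex_is", list(sex = sex))
}

#' Dose constraint on a medication order
#'
#' @param metric One of `"per_kg_per_day"`, `"per_day"`, `"per_dose"`,
#'   `"per_kg_per_hour"`, `"cumulative_total"`, `"cumulative_per_kg"`.
#' @param threshold Numeric threshold, in `unit` (per kg and/or per day as
#'   the metric dictates).
#' @param unit Mass unit of the threshold (`"mg"`, `"g"`, `"ug"`).
#' @param inclusive If `TRUE` the comparison is `>=` (as for thresholds the
#'   criteria print with a `>=` sign); the default is the strict `>` used by
#'   most printed thresholds.
#' @return A dose-constraint list for [pred_drug_present()].
#' @export
dose_exceeds <- function(metric, threshold, unit = "mg", inclusive = FALSE) {
  metric <- match.arg(metric, c("per_kg_per_day", "per_day", "per_dose",
                                "per_kg_per_hour", "cumulative_total",
                                "cumulative_per_kg"))
  list(metric = metric, threshold = as.numeric(threshold), unit = unit,
       inclusive = isTRUE(inclusive))
}

#' Duration constraint on a medication order
#'
#' @param value Numeric duration threshold (strict `>`).
#' @param unit One of `"hours"`, `"days"`, `"weeks"`, `"months"`.
#' @return A duration-constraint list for [pred_drug_present()].
#' @export
duration_exceeds <- function(value, unit) {
  unit <- match.arg(unit, c("hours", "days", "weeks", "months"))
  list(value = as.numeric(value), unit = unit)
}

#' @rdname predicate-constructors
#' @export
pred_drug_present <- function(drug, route = NULL, dose = NULL,
                              min_duration = NULL, freq_below = NULL,
                              freq_above = NULL) {
  stopifnot(is_scalar_chr(drug))
  new_predicate("drug_present", list(
    drug = drug, route = route, dose = dose, min_duration = min_duration,
    freq_below = if (!is.null(freq_below)) as.integer(freq_below),
    freq_above = if (!is.null(freq_above)) as.integer(freq_above)
  ))
}

#' Temporal window between two co-prescribed orders
#'
#' Describes when the relative timing of an index order (the anchor drug)
#' and a co-prescribed order constitutes the interaction a criterion warns
#' about. With anchor time `ta` and co-drug time `tb` (hours):
#' * `within_after`: violation when `0 <= tb - ta <= after_hours`
#'   (co-drug given within the window after the anchor);
#' * `within_before`: violation when `0 <= ta - tb <= before_hours`;
#' * `simultaneous`: violation when the two treatment intervals overlap
#'   (an order's interval runs from its start time for `duration_days`,
#'   defaulting to one day when the duration is not recorded);
#' * `required_gap_before_and_after`: the anchor must be taken at least
#'   `before_hours` before or `after_hours` after the co-drug; violation
#'   when `-before_hours < ta - tb < after_hours`.
#'
#' When both orders lack timestamps but sit on the same record they are
#' treated as simultaneous; when exactly one timestamp is missing the
#' window is indeterminate.
#'
#' @param relation One of `"within_after"`, `"within_before"`,
#'   `"simultaneous"`, `"required_gap_before_and_after"`.
#' @param before_hours,after_hours Non-negative bounds in hours.
#' @return A temporal-window list.
#' @export
temporal_window <- function(relation, before_hours = NULL, after_hours = NULL) {
  relation <- match.arg(relation, c("within_after", "within_before",
                                    "simultaneous",
                                    "required_gap_before_and_after"))
  if (relation != "simultaneous" &&
      is.null(before_hours) && is.null(after_hours)) {
    stop("temporal window needs at least one bound unless simultaneous")
  }
  w <- list(relation = relation,
            before_hours = if (!is.null(before_hours)) as.numeric(before_hours),
            after_hours = if (!is.null(after_hours)) as.numeric(after_hours))
  w[!vapply(w, is.null, logical(1))]
}

#' @rdname predicate-constructors
#' @export
pred_co_prescribed <- function(anchor, drug, window, route = NULL) {
  stopifnot(is_scalar_chr(anchor), is_scalar_chr(drug))
  new_predicate("co_prescribed",
                list(anchor = anchor, drug = drug, route = route,
                     window = window))
}

#' @rdname predicate-constructors
#' @export
pred_diagnosis_present <- function(tag) {
  stopifnot(is_scalar_chr(tag))
  new_predicate("diagnosis_present", list(tag = tag))
}

#' @rdname predicate-constructors
#' @export
pred_procedure_present <- function(tag, linked_drug = NULL) {
  stopifnot(is_scalar_chr(tag))
  new_predicate("procedure_present", list(tag = tag, linked_drug = linked_drug))
}

#' @rdname predicate-constructors
#' @export
pred_drug_count_at_least <- function(drug, n) {
  new_predicate("drug_count_at_least", list(drug = drug, n = as.integer(n)))
}

#' @rdname predicate-constructors
#' @export
pred_any_medication_present <- function() new_predicate("any_medication_present")

PRED_ATOM_KINDS <- c(
  "always", "age_in_range", "gestational_age_below", "birth_weight_below",
  "current_weight_below", "is_premature", "sex_is", "drug_present",
  "co_prescribed", "diagnosis_present", "procedure_present",
  "drug_count_at_least", "any_medication_present"
)
PRED_COMBINATOR_KINDS <- c("all_of", "any_of", "not")

#' Validate a predicate tree against a lexicon and vocabulary
#'
#' Checks structural well-formedness and referential integrity: every drug
#' or class id must resolve in the lexicon and every tag in the condition
#' vocabulary. Returns a character vector of problems (empty when valid).
#'
#' @param p A `pip_predicate`.
#' @param lexicon A [drug_lexicon()].
#' @param vocabulary A [condition_vocabulary()].
#' @param where Label used to prefix reported problems.
#' @return Character vector of problem descriptions.
#' @export
validate_predicate <- function(p, lexicon, vocabulary, where = "predicate") {
  probs <- character()
  note <- function(msg) probs <<- c(probs, paste0(where, ": ", msg))
  known_drug <- function(id) {
    id %in% lexicon$drug_ids || id %in% lexicon$class_ids
  }
  known_tag <- function(id) id %in% vocabulary$tags$tag_id

  walk <- function(p) {
    if (!inherits(p, "pip_predicate") || is.null(p$kind)) {
      note("node is not a predicate")
      return(invisible())
    }
    kind <- p$kind
    if (kind %in% PRED_COMBINATOR_KINDS) {
      if (kind == "not") {
        walk(p$child)
      } else {
        if (length(p$children) == 0L) note(paste0(kind, " with no children"))
        lapply(p$children, walk)
      }
      return(invisible())
    }
    if (!kind %in% PRED_ATOM_KINDS) {
      note(paste0("unknown atom kind '", kind, "'"))
      return(invisible())
    }
    switch(kind,
      age_in_range = {
        if (!is_scalar_num(p$min_days) || !is_scalar_num(p$max_days) ||
            p$min_days < 0 || p$max_days <= p$min_days)
          note("invalid age range")
      },
      sex_is = if (!p$sex %in% c("male", "female")) note("invalid sex"),
      drug_present = {
        if (!known_drug(p$drug)) note(paste0("unresolved drug id '", p$drug, "'"))
        if (!is.null(p$dose)) {
          ok_units <- c("mg", "g", "ug", "mcg")
          if (!tolower(p$dose$unit) %in% ok_units)
            note(paste0("dose unit '", p$dose$unit, "' not a mass unit"))
        }
      },
      co_prescribed = {
        if (!known_drug(p$anchor)) note(paste0("unresolved anchor id '", p$anchor, "'"))
        if (!known_drug(p$drug)) note(paste0("unresolved drug id '", p$drug, "'"))
        w <- p$window
        if (is.null(w$relation)) {
          note("co_prescribed without window relation")
        } else if (w$relation != "simultaneous" &&
                   is.null(w$before_hours) && is.null(w$after_hours)) {
          note("temporal window without bounds")
        }
      },
      diagnosis_present = if (!known_tag(p$tag))
        note(paste0("unresolved tag '", p$tag, "'")),
      procedure_present = {
        if (!known_tag(p$tag)) note(paste0("unresolved tag '", p$tag, "'"))
        if (!is.null(p$linked_drug) && !known_drug(p$linked_drug))
          note(paste0("unresolved linked drug '", p$linked_drug, "'"))
      },
      drug_count_at_least = {
        if (!known_drug(p$drug)) note(paste0("unresolved drug id '", p$drug, "'"))
        if (!is_scalar_num(p$n) || p$n < 1) note("invalid count")
      }
    )
    invisible()
  }
  walk(p)
  probs
}

# ---- (de)serialization -------------------------------------------------

predicate_to_list <- function(p) {
  x <- unclass(p)
  if (p$kind == "not") {
    x$child <- predicate_to_list(p$child)
  } else if (p$kind %in% c("all_of", "any_of")) {
    x$children <- lapply(p$children, predicate_to_list)
  }
  x[!vapply(x, is.null, logical(1))]
}

predicate_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$kind))
  if (x$kind == "not") {
    x$child <- predicate_from_list(x$child)
  } else if (x$kind %in% c("all_of", "any_of")) {
    x$children <- lapply(x$children, predicate_from_list)
  } else {
    if (!is.null(x$min_days)) x$min_days <- as.integer(x$min_days)
    if (!is.null(x$max_days)) x$max_days <- as.integer(x$max_days)
    if (!is.null(x$n)) x$n <- as.integer(x$n)
    if (!is.null(x$freq_below)) x$freq_below <- as.integer(x$freq_below)
    if (!is.null(x$freq_above)) x$freq_above <- as.integer(x$freq_above)
    if (!is.null(x$route)) x$route <- as.character(unlist(x$route))
    # JSON does not distinguish integral doubles from integers, so pin the
    # double-typed fields back to double after a round trip.
    for (nm in c("weeks", "grams", "kg")) {
      if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
    }
    if (!is.null(x$dose)) {
      x$dose$threshold <- as.numeric(x$dose$threshold)
      x$dose$inclusive <- isTRUE(x$dose$inclusive)
    }
    if (!is.null(x$min_duration)) {
      x$min_duration$value <- as.numeric(x$min_duration$value)
    }
    if (!is.null(x$window)) {
      for (nm in c("before_hours", "after_hours")) {
        if (!is.null(x$window[[nm]])) x$window[[nm]] <- as.numeric(x$window[[nm]])
      }
    }
  }
  structure(x, class = "pip_predicate")
}

#' @export
print.pip_predicate <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  if (x$kind %in% c("all_of", "any_of")) {
    cat(pad, x$kind, ":\n", sep = "")
    lapply(x$children, print, indent = indent + 1)
  } else if (x$kind == "not") {
    cat(pad, "not:\n", sep = "")
    print(x$child, indent = indent + 1)
  } else {
    extra <- setdiff(names(x), "kind")
    desc <- vapply(extra, function(nm) {
      v <- x[[nm]]
      if (is.null(v)) return(NA_character_)
      paste0(nm, "=", paste(deparse(v, nlines = 1), collapse = ""))
    }, character(1))
    desc <- desc[!is.na(desc)]
    cat(pad, x$kind,
        if (length(desc)) paste0("(", paste(desc, collapse = ", "), ")"),
        "\n", sep = "")
  }
  invisible(x)
}
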