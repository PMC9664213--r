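---
title: "Methods: knowledge representation, screening semantics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge representation, screening semantics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpip)
```

This vignette documents the design decisions behind `pedpip`: how the
criteria are encoded, how the screening engine evaluates them against
incomplete records, how severities are assigned, and what the synthetic
cohort generator does and does not guarantee.

## The knowledge base

The packaged knowledge base holds 136 explicit criteria for potentially
inappropriate prescribing in children, split into two parts:

* **non-specific** criteria (71: 68 PIM, 3 PPO), organized by
  anatomical/therapeutic drug group, which apply regardless of the
  clinical problem; and
* **disease-specific** criteria (65: 55 PIM, 10 PPO), organized by
  clinical problem (respiratory, infectious, neurological, and so on),
  whose triggers require a documented diagnosis.

A *PIM* (potentially inappropriate medication) criterion flags a drug
exposure; a *PPO* (potential prescribing omission) criterion flags a
missing co-intervention — for example, a required monitoring procedure
or protective co-prescription — in a patient who qualifies for it.

Each criterion is a small data object:

```{r}
kb <- load_knowledge_base(system.file("extdata", "kb", package = "pedpip"))
str(kb$criteria[[1]], max.level = 1)
```

* `trigger`: a predicate that must hold for the criterion to apply.
* For PIM criteria, `severity_clauses`: an ordered set of
  (predicate, severity) pairs with severities `caution` or `avoid`; the
  strongest satisfied clause wins. PPO criteria instead carry
  `required`: a predicate describing the intervention whose *absence*
  is flagged (reported with severity `omission`).
* Exceptions (`exception`, optional): a predicate that suppresses the
  flag when satisfied (for example, a diagnosis that justifies the
  exposure).
* `risk_text`: the human-readable rationale shown in reports. A few
  criteria state no rationale; these carry an empty string rather
  than invented text.

### The predicate language

Triggers are composed from thirteen atoms (`drug_present`,
`co_prescribed`, `age_in_range`, `diagnosis_present`,
`procedure_present`, `dose`/`duration`/`frequency` constraints attached
to a drug atom, anthropometric thresholds, and others) combined with
`all_of`, `any_of`, and `not`. Two atoms deserve comment:

* **`drug_present` is a rich atom.** Route, dose, minimum duration, and
  frequency constraints attached to it must all be satisfied *by the
  same order*. Encoding "intravenous paracetamol above 60 mg/kg/day"
  as separate route and dose atoms would incorrectly fire on a patient
  with a low-dose intravenous order plus a high-dose oral order.
* **`co_prescribed`** relates two drugs through a temporal window
  (described below), anchored on one of them.

### Age intervals

Ages are compared in days with half-open intervals. A stated limit of
*N* years converts with `years_to_days(N) = ceiling(N * 365.25)`, so
"under 2 years" means `[0, 731)` days and "up to 2 years" (inclusive)
means `[0, 732)`. The ceiling convention guarantees that a child who
has not yet completed the *N*-th year is always inside the interval,
including in leap years. "Neonate" is age under 29 days; "premature"
is gestational age below 37 weeks. Where a criterion says "infants"
without a bound, it is encoded as under 2 years, the broadest common
definition; narrower readings would only make the criterion fire less
often.

## Screening semantics

Records are rarely complete, so every predicate evaluates to one of
three values: *satisfied*, *not satisfied*, or *indeterminate*.
Connectives follow strong Kleene logic: a conjunction with one false
input is false even if another input is unknown; a disjunction with one
true input is true. When a criterion's overall outcome is
indeterminate, the engine reports which patient fields were missing
(`missing_inputs`), so a reviewer knows what data would settle it.

Not every absent field is "unknown":

* A missing **order duration defaults to one day** (the minimal
  exposure a written order implies).
* When **both** orders in a co-prescription lack timestamps they are
  treated as simultaneous — two undated orders on the same encounter
  are assumed concurrent. If exactly **one** timestamp is missing, the
  comparison is genuinely indeterminate.

These closed-world defaults are assumptions, not unknowns, and the test
suite's monotonicity property (removing unknown-typed information never
converts a definite outcome into the opposite definite outcome)
deliberately leaves them alone.

### Temporal windows

`co_prescribed` supports four window types over the signed start-time
difference in hours:

* `within_after` / `within_before`: the second drug starts within *H*
  hours after (respectively before) the anchor.
* `simultaneous`: the two treatment intervals overlap, using each
  order's duration (defaulting to one day).
* `required_gap_before_and_after`: the second drug starts *inside* the
  forbidden interval around the anchor (used for "separate
  administration by at least *H* hours" rules, which flag when the gap
  is violated).

### Doses

Dose thresholds compare in milligrams against one of six metrics:
per dose, per day, per kg per day, per kg per hour, cumulative total,
and cumulative per kg. A missing frequency or weight makes the derived
metrics indeterminate rather than zero. Comparison is strict (`>`) by
default, with an `inclusive` flag for criteria phrased as "at or
above". One convention worth noting: where a limit is phrased as a
single administration cap (for example chloral hydrate 1 g), it is
encoded `per_dose`; phrased as a daily maximum, `per_day` — mixing the
two changes which multi-dose regimens fire.

### Severity

For PIM criteria the report carries the strongest satisfied severity
clause: `avoid` outranks `caution`. Disease-specific rows default to
`caution` unless the criterion explicitly says to avoid the drug.
PPO hits always carry severity `omission`.

## The consensus calculator

Criteria development used a two-round expert rating process on a 1–5
scale. `compute_stats()` reports mean, standard deviation (sample),
coefficient of variation, quartiles (type-7), and the full-score rate;
`classify_consensus()` applies the rules: accept when Q1 ≥ 4, mean > 4,
and CV < 0.20; reject when Q3 ≤ 2, mean < 2, and CV < 0.20; otherwise
no consensus. The CV cut is strict, so CV = 0.20 exactly never reaches
consensus. `tally_rounds()` audits a round ledger for conservation
(entered = accepted + rejected + carried) and hand-over (next round
enters exactly what was carried plus newly proposed items).

## The synthetic cohort

`generate_cohort()` builds a cohort from its own deterministic
generator (a linear congruential RNG seeded from the configuration, so
results do not depend on R's global RNG state). A *plan* — a data
frame of `criterion_id`, `count_positives`,
`count_boundary_negatives` — plants records engineered to trigger a
chosen criterion, and records engineered to *just miss* it:

* A **planted positive** satisfies the trigger with margin and avoids
  the criterion's exceptions.
* A **boundary negative** starts from the positive construction and
  flips exactly one constraint just past its boundary, preferring the
  sharpest available edge (dose threshold first, then duration,
  frequency, anthropometrics, temporal window, and finally the
  narrowest age bound). Care is taken that flipping one branch of a
  disjunctive trigger does not land the record in a sibling branch.

All remaining records are background patients drawn to be clean: their
drugs, doses, and ages are sampled away from every criterion's firing
region. `labels.csv` records the ground truth (`flag` for planted
positives, `clean` for boundary negatives), which is what the
acceptance run scores recall and false-flag rate against.

Two limitations are worth knowing. First, realism is subordinate to
label correctness: to keep a weight-threshold criterion's sibling
branches quiet, a planted record may carry a clinically atypical
weight-for-age. Second, boundary negatives sit one notch outside the
firing region by construction, so they probe the encoded boundary —
they are not a statement about clinical gray zones near it.

## Worked example

```{r}
record <- prescription_record(
  record_id = "example-1",
  encounter_date = as.Date("2024-03-01"),
  patient = patient_profile(patient_id = "p1", age_days_at_encounter = 20,
                            sex = "male", current_weight_kg = 3.4),
  orders = list(medication_order(order_id = "o1",
                                 drug_text = "ceftriaxone",
                                 drug_id = "ceftriaxone",
                                 route = "intravenous", dose_amount = 170,
                                 frequency_per_day = 1)))
res <- screen_record(record, kb)
res$flags[, c("criterion_id", "category", "severity")]
```

A neonate on ceftriaxone triggers the corresponding use-in-neonates
criterion; the report carries the criterion's rationale in
`risk_text`.
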