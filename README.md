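# pedpip

Screening of potentially inappropriate prescribing (PIP) in children.

`pedpip` ships a machine-readable knowledge base of **136 explicit
criteria** for pediatric prescribing — 71 non-specific criteria
organized by drug group (68 potentially inappropriate medications, PIM;
3 potential prescribing omissions, PPO) and 65 disease-specific
criteria organized by clinical problem (55 PIM, 10 PPO) — together
with:

* a **screening engine** that evaluates structured prescription
  records against every criterion under three-valued logic
  (flag / clear / indeterminate, with the missing fields named);
* a **consensus calculator** for the two-round expert rating process
  used to develop such criteria (quartile/mean/CV rules plus a round
  ledger with conservation checks);
* a **synthetic cohort generator** that plants per-criterion positives
  and one-notch boundary negatives with ground-truth labels, for
  end-to-end validation; and
* a **command-line interface** with `screen`, `kb-stats`, `delphi`,
  and `simulate` subcommands.

See `vignettes/methods.Rmd` for the full account of the knowledge
representation, evaluation semantics, and generator guarantees.

## Worked example

Screen a single record in R — a 20-day-old neonate on intravenous
ceftriaxone:

```r
library(pedpip)
kb <- load_knowledge_base(system.file("extdata", "kb", package = "pedpip"))

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
#>   criterion_id category severity
#> 1          B06      PIM  caution
```

The same pipeline from the shell, using the simulator to produce a
cohort with planted ground truth and screening it back:

```sh
KB=$(Rscript -e 'cat(system.file("extdata", "kb", package = "pedpip"))')
Rscript inst/scripts/pedpip.R simulate --out demo/cohort --n 300 --seed 7 --sweep
# wrote 300 records (272 labeled plants) to demo/cohort
Rscript inst/scripts/pedpip.R screen --input demo/cohort --kb "$KB" --out demo/screened
# screened 300 records: 145 flagged (180 flags)
head -3 demo/screened/flags.csv
# "record_id","criterion_id","category","severity","matched_orders","rationale"
# "pos-A01-1","A01","PIM","avoid","pos-A01-1-o1","Risk of propofol-related infusion syndrome; ..."
# "pos-A02-1","A02","PIM","caution","pos-A02-1-o1","Risk of acute dystonia (dyskinesia); ..."
```

`--sweep` plants one positive and one boundary negative per criterion
(136 of each, 272 labeled records); `demo/cohort/labels.csv` holds the
ground truth, and every positive is flagged while every boundary
negative stays clean. Exit codes: 0 success, 2 input/schema problems,
3 knowledge-base problems, 4 usage/configuration errors.

Inspect the knowledge base composition:

```sh
Rscript inst/scripts/pedpip.R kb-stats
# Knowledge base: 136 criteria
#          part category  n
#  non_specific      PIM 68
#  non_specific      PPO  3
#      specific      PIM 55
#      specific      PPO 10
```

## Layout

* `R/` — knowledge base model, predicate language, patient model,
  screening engine, consensus calculator, cohort generator, I/O, CLI.
* `inst/extdata/kb/` — the packaged knowledge base (JSON).
* `inst/scripts/pedpip.R` — CLI entry point.
* `scripts/acceptance.R` — end-to-end acceptance run.
* `tests/testthat/` — unit, property-based, and acceptance tests,
  including an engine-independent evaluation oracle
  (`helper-oracle.R`).
* `vignettes/methods.Rmd` — methods and design decisions.
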