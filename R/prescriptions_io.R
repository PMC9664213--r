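#' Read a prescription cohort from its CSV trio
#'
#' A cohort directory holds three files. `patients.csv` has one row per
#' encounter: `record_id`, `patient_id`, `encounter_date`, `sex`,
#' `birth_date` or `age_days` (exactly one per row), `gestational_age_weeks`,
#' `birth_weight_g`, `weight_kg`, `diagnoses` (";"-separated vocabulary
#' tags), `flags` (";"-separated). `orders.csv`: `record_id`, `patient_id`,
#' `order_id`, `drug`, `dose`, `dose_unit`, `freq_per_day`, `route`,
#' `start_time` (ISO-8601, UTC), `duration_days`, `cumulative_dose`,
#' `cumulative_unit`. `procedures.csv`: `record_id`, `procedure_tag`,
#' `linked_drug`, `time`. Empty cells are missing values.
#'
#' A missing mandatory column is a fatal schema error. Per-row problems
#' (an unparseable dose, an unknown drug name) are collected in the
#' ingestion report and do not abort the read; orders with unknown drugs
#' are kept but can never match a criterion.
#'
#' @param path Directory containing the three CSVs.
#' @param lexicon A [drug_lexicon()] used to canonicalize drug names.
#' @return `list(records, report)`: the list of
#'   [prescription_record()]s and a `data.frame(file, row, record_id,
#'   problem)` ingestion report.
#' @export
read_prescriptions <- function(path, lexicon) {
  read_one <- function(fname, mandatory) {
    fp <- file.path(path, fname)
    if (!file.exists(fp)) {
      pip_abort(paste0("missing input file: ", fp), "pip_schema_error")
    }
    df <- utils::read.csv(fp, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing_cols <- setdiff(mandatory, names(df))
    if (length(missing_cols)) {
      pip_abort(paste0(fname, " missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "pip_schema_error")
    }
    df
  }
  patients <- read_one("patients.csv", c("record_id", "patient_id"))
  orders <- read_one("orders.csv", c("record_id", "drug", "dose"))
  procedures <- read_one("procedures.csv", c("record_id", "procedure_tag"))

  report <- list()
  note <- function(file, row, record_id, problem) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, row = row, record_id = record_id, problem = problem,
      stringsAsFactors = FALSE)
  }
  blank <- function(x) is.null(x) || is.na(x) || !nzchar(trimws(x))
  num_or_null <- function(x) if (blank(x)) NULL else suppressWarnings(as.numeric(x))
  chr_or_null <- function(x) if (blank(x)) NULL else trimws(x)
  split_tags <- function(x) {
    if (blank(x)) character() else {
      tags <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
      tags[nzchar(tags)]
    }
  }
  parse_time <- function(x) {
    if (blank(x)) return(NULL)
    t <- as.POSIXct(gsub("T", " ", sub("Z$", "", x)), tz = "UTC")
    if (is.na(t)) NULL else t
  }

  records <- list()
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    rid <- p$record_id
    age_days <- num_or_null(p[["age_days"]] %||% NA)
    bdate <- chr_or_null(p[["birth_date"]] %||% NA)
    patient <- tryCatch(
      patient_profile(
        patient_id = p$patient_id,
        sex = if (blank(p[["sex"]] %||% NA)) "unknown" else p$sex,
        birth_date = if (is.null(age_days) && !is.null(bdate)) as.Date(bdate),
        age_days_at_encounter = age_days,
        gestational_age_weeks = num_or_null(p[["gestational_age_weeks"]] %||% NA),
        birth_weight_g = num_or_null(p[["birth_weight_g"]] %||% NA),
        current_weight_kg = num_or_null(p[["weight_kg"]] %||% NA),
        diagnosis_tags = split_tags(p[["diagnoses"]] %||% NA),
        clinical_flags = split_tags(p[["flags"]] %||% NA)
      ),
      error = function(e) {
        note("patients.csv", i, rid, conditionMessage(e))
        NULL
      })
    if (is.null(patient)) next
    enc_date <- if (blank(p[["encounter_date"]] %||% NA)) {
      Sys.Date()
    } else as.Date(p$encounter_date)

    ord_rows <- orders[orders$record_id == rid, , drop = FALSE]
    ords <- list()
    for (j in seq_len(nrow(ord_rows))) {
      o <- ord_rows[j, ]
      orow <- which(orders$record_id == rid)[j]
      dose <- suppressWarnings(as.numeric(o$dose))
      if (is.na(dose) || dose < 0) {
        note("orders.csv", orow, rid,
             paste0("unparseable dose '", o$dose, "' for drug '", o$drug, "'"))
        dose <- 0
      }
      drug_id <- canonicalize_drug(o$drug, lexicon)
      if (is.na(drug_id)) {
        note("orders.csv", orow, rid,
             paste0("unknown drug '", o$drug, "' (will not match criteria)"))
      }
      route <- chr_or_null(o[["route"]] %||% NA)
      if (!is.null(route) && !route %in% ORDER_ROUTES) {
        note("orders.csv", orow, rid, paste0("unknown route '", route, "'"))
        route <- "other"
      }
      freq <- num_or_null(o[["freq_per_day"]] %||% NA)
      ords[[length(ords) + 1L]] <- medication_order(
        order_id = if (blank(o[["order_id"]] %||% NA))
          paste0(rid, "-o", j) else o$order_id,
        drug_text = o$drug, drug_id = drug_id,
        dose_amount = dose,
        dose_unit = if (blank(o[["dose_unit"]] %||% NA)) "mg" else o$dose_unit,
        frequency_per_day = if (!is.null(freq) && freq >= 1) freq,
        route = route,
        start_time = parse_time(o[["start_time"]] %||% NA),
        duration_days = num_or_null(o[["duration_days"]] %||% NA),
        cumulative_dose = num_or_null(o[["cumulative_dose"]] %||% NA),
        cumulative_unit = if (blank(o[["cumulative_unit"]] %||% NA)) "mg"
          else o$cumulative_unit
      )
    }
    proc_rows <- procedures[procedures$record_id == rid, , drop = FALSE]
    procs <- lapply(seq_len(nrow(proc_rows)), function(j) {
      pr <- proc_rows[j, ]
      procedure_order(
        procedure_tag = pr$procedure_tag,
        linked_drug_id = chr_or_null(pr[["linked_drug"]] %||% NA),
        time = parse_time(pr[["time"]] %||% NA)
      )
    })
    records[[length(records) + 1L]] <- prescription_record(
      record_id = rid, encounter_date = enc_date, patient = patient,
      orders = ords, procedures = procs)
  }
  report_df <- if (length(report)) do.call(rbind, report) else
    data.frame(file = character(), row = integer(), record_id = character(),
               problem = character(), stringsAsFactors = FALSE)
  list(records = records, report = report_df)
}

fmt_or_blank <- function(x, fmt = as.character) {
  if (is.null(x)) "" else fmt(x)
}
fmt_time <- function(t) {
  if (is.null(t)) "" else format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write a prescription cohort to its CSV trio
#'
#' Inverse of [read_prescriptions()]; the round trip is lossless for all
#' modeled fields.
#'
#' @param records List of [prescription_record()]s.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(records, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pat <- lapply(records, function(r) {
    p <- r$patient
    data.frame(
      record_id = r$record_id, patient_id = p$patient_id,
      encounter_date = format(r$encounter_date, "%Y-%m-%d"),
      sex = p$sex,
      birth_date = fmt_or_blank(p$birth_date,
                                function(d) format(d, "%Y-%m-%d")),
      age_days = fmt_or_blank(p$age_days_at_encounter),
      gestational_age_weeks = fmt_or_blank(p$gestational_age_weeks),
      birth_weight_g = fmt_or_blank(p$birth_weight_g),
      weight_kg = fmt_or_blank(p$current_weight_kg),
      diagnoses = paste(p$diagnosis_tags, collapse = ";"),
      flags = paste(p$clinical_flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  ord <- list()
  prc <- list()
  for (r in records) {
    for (o in r$orders) {
      ord[[length(ord) + 1L]] <- data.frame(
        record_id = r$record_id, patient_id = r$patient$patient_id,
        order_id = o$order_id, drug = o$drug_text,
        dose = as.character(o$dose_amount), dose_unit = o$dose_unit,
        freq_per_day = fmt_or_blank(o$frequency_per_day),
        route = fmt_or_blank(o$route),
        start_time = fmt_time(o$start_time),
        duration_days = fmt_or_blank(o$duration_days),
        cumulative_dose = fmt_or_blank(o$cumulative_dose),
        cumulative_unit = o$cumulative_unit %||% "mg",
        stringsAsFactors = FALSE)
    }
    for (pr in r$procedures) {
      prc[[length(prc) + 1L]] <- data.frame(
        record_id = r$record_id, procedure_tag = pr$procedure_tag,
        linked_drug = fmt_or_blank(pr$linked_drug_id),
        time = fmt_time(pr$time), stringsAsFactors = FALSE)
    }
  }
  empty_orders <- data.frame(
    record_id = character(), patient_id = character(), order_id = character(),
    drug = character(), dose = character(), dose_unit = character(),
    freq_per_day = character(), route = character(), start_time = character(),
    duration_days = character(), cumulative_dose = character(),
    cumulative_unit = character(), stringsAsFactors = FALSE)
  empty_procs <- data.frame(
    record_id = character(), procedure_tag = character(),
    linked_drug = character(), time = character(), stringsAsFactors = FALSE)
  empty_pat <- data.frame(
    record_id = character(), patient_id = character(),
    encounter_date = character(), sex = character(), birth_date = character(),
    age_days = character(), gestational_age_weeks = character(),
    birth_weight_g = character(), weight_kg = character(),
    diagnoses = character(), flags = character(), stringsAsFactors = FALSE)
  utils::write.csv(if (length(pat)) do.call(rbind, pat) else empty_pat,
                   file.path(path, "patients.csv"), row.names = FALSE)
  utils::write.csv(if (length(ord)) do.call(rbind, ord) else empty_orders,
                   file.path(path, "orders.csv"), row.names = FALSE)
  utils::write.csv(if (length(prc)) do.call(rbind, prc) else empty_procs,
                   file.path(path, "procedures.csv"), row.names = FALSE)
  invisible(path)
}
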