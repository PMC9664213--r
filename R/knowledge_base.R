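#' Drug lexicon: canonical drugs, synonyms and closed drug classes
#'
#' The criteria reference medicines either individually or through drug
#' classes (e.g. aminoglycoside antibiotics). Classes are closed member
#' lists seeded from the enumerations the criteria print; a class never
#' matches a drug outside its member list.
#'
#' @param drugs List of `list(canonical_id, label, synonyms)` entries.
#' @param classes List of `list(class_id, label, member_ids)` entries.
#' @return A `pip_lexicon` with precomputed lookup tables: `drug_ids`,
#'   `class_ids`, `members` (class id -> member drug ids) and
#'   `synonym_map` (case-folded name -> canonical id).
#' @export
drug_lexicon <- function(drugs = list(), classes = list()) {
  drug_ids <- vapply(drugs, `[[`, character(1), "canonical_id")
  if (anyDuplicated(drug_ids)) {
    pip_abort(paste0("duplicate drug id: ",
                     paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", ")),
              "pip_kb_error")
  }
  class_ids <- vapply(classes, `[[`, character(1), "class_id")
  if (anyDuplicated(class_ids) || any(class_ids %in% drug_ids)) {
    pip_abort("class ids must be unique and distinct from drug ids",
              "pip_kb_error")
  }
  members <- list()
  for (cl in classes) {
    bad <- setdiff(cl$member_ids, drug_ids)
    if (length(bad)) {
      pip_abort(paste0("class '", cl$class_id, "' references unknown drugs: ",
                       paste(bad, collapse = ", ")), "pip_kb_error")
    }
    members[[cl$class_id]] <- as.character(cl$member_ids)
  }
  synonym_map <- list()
  for (d in drugs) {
    names_all <- unique(tolower(trimws(c(d$canonical_id, d$label, d$synonyms))))
    for (nm in names_all) {
      prev <- synonym_map[[nm]]
      if (!is.null(prev) && prev != d$canonical_id) {
        pip_abort(paste0("synonym '", nm, "' maps to both '", prev,
                         "' and '", d$canonical_id, "'"), "pip_kb_error")
      }
      synonym_map[[nm]] <- d$canonical_id
    }
  }
  structure(list(drugs = drugs, classes = classes, drug_ids = drug_ids,
                 class_ids = class_ids, members = members,
                 synonym_map = synonym_map),
            class = "pip_lexicon")
}

#' Resolve a drug or class id to the set of member drug ids
#' @param lexicon A [drug_lexicon()].
#' @param id Drug or class id.
#' @return Character vector of canonical drug ids.
#' @export
resolve_drug_ids <- function(lexicon, id) {
  if (id %in% lexicon$class_ids) lexicon$members[[id]] else id
}

#' Condition vocabulary
#'
#' Controlled tags for the disease contexts, clinical flags and procedure
#' types the criteria reference (e.g. `"asthma"`, `"immunocompromised"`,
#' `"tdm"`, `"skin_test"`). Diagnoses arrive on records already mapped to
#' these tags.
#'
#' @param tags `data.frame` with columns `tag_id`, `label`.
#' @return A `pip_vocabulary`.
#' @export
condition_vocabulary <- function(tags) {
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  stopifnot(all(c("tag_id", "label") %in% names(tags)))
  if (anyDuplicated(tags$tag_id)) {
    pip_abort("duplicate tag ids in vocabulary", "pip_kb_error")
  }
  rownames(tags) <- NULL
  structure(list(tags = tags[, c("tag_id", "label")]), class = "pip_vocabulary")
}

#' One screening criterion
#'
#' A PIM criterion fires when its trigger predicate is satisfied and its
#' exception predicate (if any) is not; the reported severity is the
#' highest severity (`avoid` > `caution`) among its satisfied severity
#' clauses. A PPO criterion fires when trigger holds, the exception does
#' not, and the required action (a drug or procedure that should accompany
#' the triggering situation) is absent from the record.
#'
#' @param criterion_id Unique id.
#' @param part `"non_specific"` or `"specific"` (which criteria table the
#'   rule belongs to).
#' @param category `"PIM"` or `"PPO"`.
#' @param group Table section heading (e.g. `"Nervous system"`).
#' @param trigger Trigger [predicate][predicate-constructors].
#' @param exception Optional exception predicate.
#' @param severity_clauses For PIM: list of `list(severity, predicate)`
#'   with severity `"avoid"` or `"caution"`.
#' @param required_action For PPO: predicate describing the required
#'   accompanying drug/procedure.
#' @param risk_text Human-readable risk / recommendation text.
#' @param subgroup Optional sub-heading within the group.
#' @param provenance `list(table, row_label)` locating the source row;
#'   may carry a free-text `note`.
#' @return A `pip_criterion`.
#' @export
criterion <- function(criterion_id, part, category, group, trigger,
                      exception = NULL, severity_clauses = list(),
                      required_action = NULL, risk_text = "",
                      subgroup = NULL, provenance = list()) {
  part <- match.arg(part, c("non_specific", "specific"))
  category <- match.arg(category, c("PIM", "PPO"))
  if (category == "PIM") {
    if (length(severity_clauses) == 0L)
      pip_abort(paste0(criterion_id, ": PIM criterion needs >=1 severity clause"),
                "pip_kb_error")
    if (!is.null(required_action))
      pip_abort(paste0(criterion_id, ": PIM criterion cannot carry required_action"),
                "pip_kb_error")
    for (sc in severity_clauses) {
      if (!sc$severity %in% c("avoid", "caution"))
        pip_abort(paste0(criterion_id, ": invalid severity '", sc$severity, "'"),
                  "pip_kb_error")
    }
  } else {
    if (is.null(required_action))
      pip_abort(paste0(criterion_id, ": PPO criterion needs required_action"),
                "pip_kb_error")
    if (length(severity_clauses))
      pip_abort(paste0(criterion_id, ": PPO criterion cannot carry severity clauses"),
                "pip_kb_error")
  }
  structure(list(criterion_id = criterion_id, part = part, category = category,
                 group = group, subgroup = subgroup, trigger = trigger,
                 exception = exception, severity_clauses = severity_clauses,
                 required_action = required_action,
                 risk_text = as.character(risk_text),
                 provenance = provenance),
            class = "pip_criterion")
}

#' Assemble a knowledge base
#'
#' @param version Schema/content version string (mandatory).
#' @param criteria List of [criterion()] objects.
#' @param lexicon A [drug_lexicon()].
#' @param vocabulary A [condition_vocabulary()].
#' @return A `pip_kb`.
#' @export
knowledge_base <- function(version, criteria, lexicon, vocabulary) {
  ids <- vapply(criteria, `[[`, character(1), "criterion_id")
  if (anyDuplicated(ids)) {
    pip_abort(paste0("duplicate criterion id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "pip_kb_duplicate_id_error")
  }
  criteria <- criteria[order(ids)]
  structure(list(version = as.character(version), criteria = criteria,
                 lexicon = lexicon, vocabulary = vocabulary),
            class = "pip_kb")
}

#' Path to the packaged knowledge base
#'
#' The packaged knowledge base encodes the full set of 136 pediatric PIP
#' criteria as a split JSON document (manifest plus lexicon, vocabulary and
#' per-part criteria files).
#'
#' @return Directory path suitable for [load_knowledge_base()].
#' @export
pip_kb_path <- function() {
  system.file("extdata", "kb", package = "pedpip", mustWork = TRUE)
}

# ---- serialization -----------------------------------------------------

criterion_to_list <- function(cr) {
  out <- list(
    criterion_id = cr$criterion_id, part = cr$part, category = cr$category,
    group = cr$group, subgroup = cr$subgroup,
    trigger = predicate_to_list(cr$trigger),
    exception = if (!is.null(cr$exception)) predicate_to_list(cr$exception),
    severity_clauses = if (length(cr$severity_clauses)) {
      lapply(cr$severity_clauses, function(sc)
        list(severity = sc$severity, predicate = predicate_to_list(sc$predicate)))
    },
    required_action = if (!is.null(cr$required_action))
      predicate_to_list(cr$required_action),
    risk_text = cr$risk_text,
    provenance = cr$provenance
  )
  out[!vapply(out, is.null, logical(1))]
}

criterion_from_list <- function(x) {
  criterion(
    criterion_id = x$criterion_id, part = x$part, category = x$category,
    group = x$group, subgroup = x$subgroup %||% NULL,
    trigger = predicate_from_list(x$trigger),
    exception = if (!is.null(x$exception)) predicate_from_list(x$exception),
    severity_clauses = if (!is.null(x$severity_clauses)) {
      lapply(x$severity_clauses, function(sc)
        list(severity = sc$severity,
             predicate = predicate_from_list(sc$predicate)))
    } else list(),
    required_action = if (!is.null(x$required_action))
      predicate_from_list(x$required_action),
    risk_text = x$risk_text %||% "",
    provenance = lapply(x$provenance %||% list(), as.character)
  )
}

lexicon_to_list <- function(lex) {
  list(
    drugs = lapply(lex$drugs, function(d)
      list(canonical_id = d$canonical_id, label = d$label,
           synonyms = as.list(d$synonyms %||% character()))),
    classes = lapply(lex$classes, function(cl)
      list(class_id = cl$class_id, label = cl$label,
           member_ids = as.list(cl$member_ids)))
  )
}

lexicon_from_list <- function(x) {
  drug_lexicon(
    drugs = lapply(x$drugs %||% list(), function(d)
      list(canonical_id = d$canonical_id, label = d$label,
           synonyms = as.character(unlist(d$synonyms)))),
    classes = lapply(x$classes %||% list(), function(cl)
      list(class_id = cl$class_id, label = cl$label,
           member_ids = as.character(unlist(cl$member_ids))))
  )
}

vocabulary_to_list <- function(voc) {
  list(tags = lapply(seq_len(nrow(voc$tags)), function(i)
    list(tag_id = voc$tags$tag_id[i], label = voc$tags$label[i])))
}

vocabulary_from_list <- function(x) {
  tags <- x$tags %||% list()
  condition_vocabulary(data.frame(
    tag_id = vapply(tags, `[[`, character(1), "tag_id"),
    label = vapply(tags, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  ))
}

kb_to_list <- function(kb) {
  list(version = kb$version,
       lexicon = lexicon_to_list(kb$lexicon),
       vocabulary = vocabulary_to_list(kb$vocabulary),
       criteria = lapply(kb$criteria, criterion_to_list))
}

kb_from_list <- function(x, source = "knowledge base") {
  if (is.null(x$version)) {
    pip_abort(paste0(source, ": missing mandatory version string"),
              "pip_kb_schema_error")
  }
  lexicon <- lexicon_from_list(x$lexicon %||% list())
  vocabulary <- if (!is.null(x$vocabulary)) {
    vocabulary_from_list(x$vocabulary)
  } else {
    condition_vocabulary(data.frame(tag_id = character(), label = character()))
  }
  criteria <- lapply(x$criteria %||% list(), function(cx) {
    tryCatch(criterion_from_list(cx), error = function(e) {
      pip_abort(paste0(source, ": invalid criterion entry '",
                       cx$criterion_id %||% "<no id>", "': ",
                       conditionMessage(e)), "pip_kb_schema_error")
    })
  })
  kb <- knowledge_base(x$version, criteria, lexicon, vocabulary)
  probs <- kb_integrity_problems(kb)
  if (length(probs)) {
    pip_abort(paste0(source, ": referential integrity violations:\n  ",
                     paste(probs, collapse = "\n  ")),
              "pip_kb_integrity_error")
  }
  kb
}

criterion_predicates <- function(cr) {
  preds <- list(trigger = cr$trigger)
  if (!is.null(cr$exception)) preds$exception <- cr$exception
  if (!is.null(cr$required_action)) preds$required_action <- cr$required_action
  for (i in seq_along(cr$severity_clauses)) {
    preds[[paste0("severity_clause_", i)]] <- cr$severity_clauses[[i]]$predicate
  }
  preds
}

kb_integrity_problems <- function(kb) {
  probs <- character()
  for (cr in kb$criteria) {
    preds <- criterion_predicates(cr)
    for (nm in names(preds)) {
      probs <- c(probs, validate_predicate(
        preds[[nm]], kb$lexicon, kb$vocabulary,
        where = paste0(cr$criterion_id, "/", nm)))
    }
  }
  probs
}

#' Read a knowledge base document
#'
#' Accepts a single JSON document (canonical), a YAML document with the
#' same structure, or a directory holding a `manifest.json` that names the
#' lexicon, vocabulary and criteria files (the layout the packaged
#' knowledge base uses). Loading is deterministic; every drug, class and
#' tag reference is checked and an unresolved reference or duplicate
#' criterion id is an error.
#'
#' @param path File or directory path.
#' @return A fully resolved `pip_kb`.
#' @seealso [save_knowledge_base()], [pip_kb_path()]
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) {
    pip_abort(paste0("knowledge base not found: ", path), "pip_kb_error")
  }
  if (dir.exists(path)) {
    manifest_path <- file.path(path, "manifest.json")
    if (!file.exists(manifest_path)) {
      pip_abort(paste0("knowledge base directory lacks manifest.json: ", path),
                "pip_kb_schema_error")
    }
    man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
    read_part <- function(fname) {
      fp <- file.path(path, fname)
      if (!file.exists(fp))
        pip_abort(paste0("manifest references missing file: ", fname),
                  "pip_kb_schema_error")
      jsonlite::fromJSON(fp, simplifyVector = FALSE)
    }
    doc <- list(version = man$version,
                lexicon = read_part(man$lexicon_file),
                vocabulary = read_part(man$vocabulary_file),
                criteria = do.call(c, lapply(man$criteria_files, function(f)
                  read_part(f)$criteria)))
    kb_from_list(doc, source = path)
  } else {
    ext <- tolower(tools::file_ext(path))
    doc <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    }
    kb_from_list(doc, source = path)
  }
}

#' Write a knowledge base document
#'
#' @param kb A `pip_kb`.
#' @param path Target path. A path ending in `.json` or `.yaml`/`.yml`
#'   writes a single document; a directory path writes the split
#'   manifest layout with criteria grouped by part.
#' @return `path`, invisibly.
#' @export
save_knowledge_base <- function(kb, path) {
  ext <- tolower(tools::file_ext(path))
  doc <- kb_to_list(kb)
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    wj <- function(x, f) jsonlite::write_json(
      x, file.path(path, f), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = FALSE)
    parts <- split(doc$criteria,
                   vapply(kb$criteria, `[[`, character(1), "part"))
    crit_files <- character()
    for (part in names(parts)) {
      f <- paste0("criteria_", part, ".json")
      wj(list(criteria = unname(parts[[part]])), f)
      crit_files <- c(crit_files, f)
    }
    wj(doc$lexicon, "lexicon.json")
    wj(doc$vocabulary, "vocabulary.json")
    wj(list(version = doc$version, lexicon_file = "lexicon.json",
            vocabulary_file = "vocabulary.json",
            criteria_files = as.list(crit_files)), "manifest.json")
  }
  invisible(path)
}

# ---- validation and counting ------------------------------------------

#' Validate a knowledge base and summarize its composition
#'
#' Produces the counts by part and category, counts per group, and a list
#' of violations (referential integrity, duplicate provenance rows,
#' category/field inconsistencies). Violations are reported, not raised.
#'
#' @param kb A `pip_kb`.
#' @return A `pip_validation` list: `n_criteria`, `counts`
#'   (`data.frame(part, category, n)`), `group_counts`
#'   (`data.frame(part, group, n)`), `violations` (character).
#' @export
validate_knowledge_base <- function(kb) {
  parts <- vapply(kb$criteria, `[[`, character(1), "part")
  cats <- vapply(kb$criteria, `[[`, character(1), "category")
  groups <- vapply(kb$criteria, `[[`, character(1), "group")

  counts <- as.data.frame(table(part = parts, category = cats),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[order(counts$part, counts$category), , drop = FALSE]
  rownames(counts) <- NULL
  group_counts <- as.data.frame(table(part = parts, group = groups),
                                responseName = "n", stringsAsFactors = FALSE)
  group_counts <- group_counts[group_counts$n > 0, , drop = FALSE]
  group_counts <- group_counts[order(group_counts$part, group_counts$group), ,
                               drop = FALSE]
  rownames(group_counts) <- NULL

  violations <- kb_integrity_problems(kb)
  row_labels <- vapply(kb$criteria, function(cr)
    paste0(cr$provenance$table %||% "", "::", cr$provenance$row_label %||% ""),
    character(1))
  dup <- row_labels[duplicated(row_labels) & nzchar(gsub("::", "", row_labels))]
  if (length(dup)) {
    violations <- c(violations,
                    paste0("duplicate provenance row: ", unique(dup)))
  }
  structure(list(n_criteria = length(kb$criteria), counts = counts,
                 group_counts = group_counts, violations = violations),
            class = "pip_validation")
}

#' @export
print.pip_validation <- function(x, ...) {
  cat("Knowledge base:", x$n_criteria, "criteria\n\n")
  print(x$counts, row.names = FALSE)
  cat("\nPer group:\n")
  print(x$group_counts, row.names = FALSE)
  if (length(x$violations)) {
    cat("\nViolations:\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  } else {
    cat("\nNo violations.\n")
  }
  invisible(x)
}

#' Count criteria matching a filter
#'
#' @param kb A `pip_kb`.
#' @param part,category,group Optional filter values; criteria must match
#'   all supplied fields. An unknown group name is an error.
#' @return Integer count.
#' @export
count_criteria <- function(kb, part = NULL, category = NULL, group = NULL) {
  keep <- rep(TRUE, length(kb$criteria))
  if (!is.null(part)) {
    part <- match.arg(part, c("non_specific", "specific"))
    keep <- keep & vapply(kb$criteria, `[[`, character(1), "part") == part
  }
  if (!is.null(category)) {
    category <- match.arg(category, c("PIM", "PPO"))
    keep <- keep & vapply(kb$criteria, `[[`, character(1), "category") == category
  }
  if (!is.null(group)) {
    all_groups <- unique(vapply(kb$criteria, `[[`, character(1), "group"))
    if (!group %in% all_groups) {
      pip_abort(paste0("unknown group: '", group, "'"), "pip_kb_error")
    }
    keep <- keep & vapply(kb$criteria, `[[`, character(1), "group") == group
  }
  sum(keep)
}

#' @export
print.pip_kb <- function(x, ...) {
  cat("<pedpip knowledge base> version", x$version, "-",
      length(x$criteria), "criteria,",
      length(x$lexicon$drugs), "drugs,",
      length(x$lexicon$classes), "classes,",
      nrow(x$vocabulary$tags), "tags\n")
  invisible(x)
}
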