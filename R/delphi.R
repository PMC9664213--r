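#' Modified-Delphi consensus statistics for one proposition
#'
#' Panelists rate each candidate proposition on a 5-point Likert scale
#' (1 = completely disagree, 5 = completely agree). Per proposition the
#' panel response is summarized by the mean score, standard deviation,
#' coefficient of variation (CV = sd / mean), median, quartiles, IQR and
#' the full score rate (the proportion of panelists awarding 5 points).
#'
#' @param ratings Integer vector of ratings, each in 1..5, length >= 1.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()];
#'   the default 7 is linear interpolation between order statistics, the
#'   spreadsheet convention (Excel `QUARTILE.INC`).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#' @return A `pip_consensus_stats` list: `n`, `mean`, `sd`, `cv`, `median`,
#'   `q1`, `q3`, `iqr`, `full_score_rate`, plus the conventions used.
#' @export
compute_stats <- function(ratings, quartile_type = 7, sd_type = "sample") {
  if (length(ratings) == 0L) {
    pip_abort("empty rating vector", "pip_input_error")
  }
  if (any(is.na(ratings)) || any(ratings != as.integer(ratings)) ||
      any(ratings < 1) || any(ratings > 5)) {
    pip_abort("ratings must be integers in 1..5", "pip_input_error")
  }
  sd_type <- match.arg(sd_type, c("sample", "population"))
  ratings <- as.numeric(ratings)
  n <- length(ratings)
  m <- mean(ratings)
  s <- if (n == 1L) 0 else stats::sd(ratings)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  q <- stats::quantile(ratings, probs = c(0.25, 0.5, 0.75),
                       type = quartile_type, names = FALSE)
  structure(list(
    n = n, mean = m, sd = s, cv = s / m,
    median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
    full_score_rate = mean(ratings == 5),
    quartile_type = quartile_type, sd_type = sd_type
  ), class = "pip_consensus_stats")
}

#' Classify panel consensus from the summary statistics
#'
#' The predefined consensus rules: the panel *rejects* a proposition when
#' the upper quartile is <= 2 points, the mean score is < 2 points and the
#' CV is < 0.20; it *accepts* when the lower quartile is >= 4, the mean
#' score is > 4 points and the CV is < 0.20. Every other configuration is
#' a lack of consensus. The CV cut is strict (`< 0.20`); a CV of exactly
#' 0.20 never reaches consensus.
#'
#' @param s A `pip_consensus_stats` from [compute_stats()].
#' @return `"accept"`, `"reject"` or `"no_consensus"`.
#' @export
classify_consensus <- function(s) {
  if (s$q3 <= 2 && s$mean < 2 && s$cv < 0.20) return("reject")
  if (s$q1 >= 4 && s$mean > 4 && s$cv < 0.20) return("accept")
  "no_consensus"
}

#' Summarize and classify a table of Delphi ratings
#'
#' @param ratings `data.frame` with columns `proposition_id`, `round`,
#'   `rating` (and optionally `panelist_id`).
#' @param quartile_type,sd_type Conventions passed to [compute_stats()].
#' @return `data.frame` with one row per proposition per round: the
#'   statistics and the consensus status.
#' @export
delphi_table <- function(ratings, quartile_type = 7, sd_type = "sample") {
  stopifnot(all(c("proposition_id", "round", "rating") %in% names(ratings)))
  keys <- unique(ratings[, c("proposition_id", "round")])
  keys <- keys[order(keys$round, keys$proposition_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ratings$proposition_id == keys$proposition_id[i] &
      ratings$round == keys$round[i]
    s <- compute_stats(ratings$rating[sel], quartile_type, sd_type)
    data.frame(proposition_id = keys$proposition_id[i],
               round = keys$round[i], n = s$n, mean = s$mean, sd = s$sd,
               cv = s$cv, median = s$median, q1 = s$q1, q3 = s$q3,
               iqr = s$iqr, full_score_rate = s$full_score_rate,
               status = classify_consensus(s),
               quartile_type = quartile_type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally multi-round Delphi proposition bookkeeping
#'
#' Each survey round receives a set of propositions; some reach consensus
#' for acceptance, some for rejection, and the remainder are revised and
#' carried into the next round, possibly joined by new propositions the
#' panel proposed. Propositions still without consensus after the final
#' round are adjudicated manually; `adjudicated_retained` of them are
#' kept. The final retained count is the sum of per-round acceptances plus
#' the adjudicated retentions.
#'
#' @param rounds List of per-round count lists:
#'   `list(entered, accepted, rejected, carried, new_next_round = 0)`.
#'   Conservation (`entered == accepted + rejected + carried`) and
#'   hand-over (`entered[r+1] == carried[r] + new_next_round[r]`) are
#'   enforced.
#' @param adjudicated_retained Number of final-round carried propositions
#'   retained after manual adjudication (the remainder are deleted).
#' @return A `pip_round_ledger`: the per-round table plus `final_retained`.
#' @export
tally_rounds <- function(rounds, adjudicated_retained = 0) {
  tab <- do.call(rbind, lapply(seq_along(rounds), function(i) {
    r <- rounds[[i]]
    data.frame(round = i, entered = r$entered, accepted = r$accepted,
               rejected = r$rejected, carried = r$carried,
               new_next_round = r$new_next_round %||% 0,
               stringsAsFactors = FALSE)
  }))
  bad <- with(tab, entered != accepted + rejected + carried)
  if (any(bad)) {
    pip_abort(paste0("conservation violated in round ",
                     paste(tab$round[bad], collapse = ", "),
                     ": entered != accepted + rejected + carried"),
              "pip_ledger_error")
  }
  if (nrow(tab) > 1) {
    expect_in <- tab$carried[-nrow(tab)] + tab$new_next_round[-nrow(tab)]
    mism <- tab$entered[-1] != expect_in
    if (any(mism)) {
      pip_abort(paste0("round hand-over violated entering round ",
                       paste(tab$round[-1][mism], collapse = ", ")),
                "pip_ledger_error")
    }
  }
  final_carried <- tab$carried[nrow(tab)]
  if (adjudicated_retained > final_carried) {
    pip_abort("adjudicated_retained exceeds final-round carried propositions",
              "pip_ledger_error")
  }
  structure(list(
    rounds = tab,
    adjudicated_retained = adjudicated_retained,
    final_retained = sum(tab$accepted) + adjudicated_retained
  ), class = "pip_round_ledger")
}

#' @export
print.pip_round_ledger <- function(x, ...) {
  print(x$rounds, row.names = FALSE)
  cat("Adjudicated retained:", x$adjudicated_retained,
      "| Final retained:", x$final_retained, "\n")
  invisible(x)
}

#' Read a Delphi ratings CSV
#'
#' Expected columns: `proposition_id`, `round`, `panelist_id`, `rating`.
#' A non-integer or out-of-range rating is an error naming the row.
#'
#' @param path CSV path.
#' @return `data.frame` of ratings.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    pip_abort(paste0("ratings file not found: ", path), "pip_input_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("proposition_id", "round", "rating")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pip_abort(paste0("ratings file missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "pip_schema_error")
  }
  rating <- suppressWarnings(as.numeric(df$rating))
  bad <- is.na(rating) | rating != round(rating) | rating < 1 | rating > 5
  if (any(bad)) {
    pip_abort(paste0("invalid rating at row(s) ",
                     paste(which(bad), collapse = ", "),
                     " (must be an integer 1..5)"),
              "pip_input_error")
  }
  df$rating <- as.integer(rating)
  df$round <- as.integer(df$round)
  df
}
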