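#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert an age in years to whole days
#'
#' Encodes the criteria's age phrases over whole postnatal days. An age
#' printed as "< N years" becomes the half-open day range `[0, years_to_days(N))`:
#' the bound is the smallest whole number of days at or past the exact
#' calendar age `N * 365.25` days, so every child strictly younger than N
#' years falls inside the range and every child at or past the Nth birthday
#' falls outside it.
#'
#' @param years Age in years (scalar, >= 0).
#' @return Integer number of days.
#' @examples
#' years_to_days(2)  # 731
#' @export
years_to_days <- function(years) {
  stopifnot(is.numeric(years), length(years) == 1L, years >= 0)
  as.integer(ceiling(years * 365.25))
}

#' Convert months to days (1 month = 30.44 days)
#' @param months Number of months.
#' @return Number of days (numeric).
#' @export
months_to_days <- function(months) months * 30.44

# Duration unit -> days
duration_to_days <- function(value, unit) {
  switch(unit,
    hours  = value / 24,
    days   = value,
    weeks  = value * 7,
    months = value * 30.44,
    stop("unknown duration unit: ", unit)
  )
}

# Mass unit -> milligrams. Accepts the spellings used in prescription data.
mass_to_mg <- function(amount, unit) {
  u <- tolower(trimws(unit))
  factor <- switch(u,
    mg = 1, g = 1000,
    ug = 0.001, mcg = 0.001, "µg" = 0.001, "μg" = 0.001,
    NA_real_
  )
  if (is.na(factor)) stop("unknown mass unit: ", unit, call. = FALSE)
  amount * factor
}

# Round-half-up percentage, as commonly printed (11/16 -> 69).
percent_round <- function(x, digits = 0) {
  p <- x * 100
  floor(p * 10^digits + 0.5) / 10^digits
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

pip_abort <- function(msg, class) {
  # Specialized knowledge-base conditions inherit the family class so
  # one handler can catch them all.
  classes <- class
  if (startsWith(class, "pip_kb_")) classes <- c(classes, "pip_kb_error")
  stop(structure(
    class = unique(c(classes, "pip_error", "error", "condition")),
    list(message = msg, call = sys.call(-1))
  ))
}
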