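# Internal helpers shared across modules.
#
# All calendar arithmetic is done in integer days on R `Date` objects
# (internally days since 1970-01-01); "month" means a fixed 30-day block and
# "year" a fixed 365-day block wherever a window is defined in calendar words.

DAYS_PER_MONTH <- 30L

#' Difference between two dates in whole days
#' @param later,earlier `Date` vectors.
#' @return Integer vector, `later - earlier` in days (same-day = 0).
#' @keywords internal
days_between <- function(later, earlier) {
  as.integer(as.numeric(later) - as.numeric(earlier))
}

#' Lower-interpolation (type 1) sample quantile
#'
#' The convention used for every descriptive percentile in this package: the
#' smallest order statistic x_(k) with k = ceiling(n * tau). Matching this
#' convention in [fit_quantile_regression()]'s tie-break makes unadjusted
#' median-regression coefficients equal differences of group medians exactly.
#'
#' @param x Numeric vector (missing values dropped).
#' @param tau Quantile level(s) in (0, 1].
#' @return Numeric vector of quantiles.
#' @export
#' @examples
#' quantile_lower(c(1, 2, 8, 9), 0.5) # 2, not 5
quantile_lower <- function(x, tau) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(tau)))
  k <- pmin(pmax(ceiling(n * tau), 1L), n)
  x[k]
}

# stopifnot-style check that raises a classed configuration error naming the
# offending field.
check_config <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(
      sprintf("Invalid configuration field `%s`: %s", field, msg),
      class = "dxinterval_config_error",
      field = field
    )
  }
  invisible(TRUE)
}

data_error <- function(msg, ...) {
  abort(msg, class = "dxinterval_data_error", ...)
}

# Draw n integer dates uniformly from [from, to] (Date scalars, inclusive).
runif_dates <- function(n, from, to) {
  as.Date(
    sample.int(as.integer(to) - as.integer(from) + 1L, n, replace = TRUE) - 1L +
      as.integer(from),
    origin = "1970-01-01"
  )
}

`%!in%` <- function(x, table) !(x %in% table)

# Fill in optional encounter columns so minimal fixtures (person_id, date,
# diagnosis_code, ...) can be fed to every stage.
normalize_encounters <- function(encounters) {
  n <- nrow(encounters)
  defaults <- list(
    encounter_id = sprintf("E%08d", seq_len(n)),
    setting = rep("physician_claim", n),
    provider_specialty = rep("other", n),
    provider_id = rep(NA_character_, n),
    referring_provider_id = rep(NA_character_, n),
    is_procedure = rep(FALSE, n),
    procedure_kind = rep("none", n),
    is_symptom_code = rep(FALSE, n)
  )
  for (col in names(defaults)) {
    if (is.null(encounters[[col]])) encounters[[col]] <- defaults[[col]]
  }
  encounters
}
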