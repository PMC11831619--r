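# Cohort construction: inclusion/exclusion rules, hierarchical severe
# psychiatric illness (SPI) exposure classification, analysis covariates.

# exposure window bounds, days before diagnosis (both endpoints inclusive):
# 5 years = 1825 days back to 6 months = 183 days
SPI_WINDOW_MAX <- 1825L
SPI_WINDOW_MIN <- 183L

#' Apply the cohort inclusion/exclusion rules
#'
#' Excludes, in rule order: non-qualifying tumor site (kept sites are C18.0
#' and C18.2–C18.9), age under 18 at diagnosis, under two years of coverage
#' before diagnosis (exactly two years is sufficient), an invalid death date
#' (death recorded before diagnosis), death-certificate-only diagnoses, and a
#' prior or synchronous other malignancy. Each excluded person appears once in
#' the ledger with the first rule that removed them. Exclusion for an
#' inconclusive mental-health history happens in [build_cohort()], and
#' exclusion for an unidentifiable first contact after interval construction;
#' both are folded into the same ledger format upstream.
#'
#' @param persons,cancers Person registry and cancer registry tables (one
#'   index cancer row per person).
#' @param min_age Minimum age at diagnosis in years (default 18).
#' @param min_coverage_days Minimum pre-diagnosis coverage (default 730).
#' @return A list: `included` (person ids), `ledger` (tibble of
#'   `person_id`, `reason`), `counts` (named exclusion counts, in rule order).
#' @export
apply_exclusions <- function(persons, cancers, min_age = 18,
                             min_coverage_days = 730L) {
  dup <- cancers$person_id[duplicated(cancers$person_id)]
  if (length(dup)) {
    data_error(sprintf("Duplicate index cancer rows for person(s): %s",
                       paste(head(unique(dup), 5), collapse = ", ")))
  }
  d <- dplyr::inner_join(persons, cancers, by = "person_id")
  keep_sites <- c("C18.0", paste0("C18.", 2:9))
  age <- days_between(d$diagnosis_date, d$birth_date) / 365.25
  coverage <- days_between(d$diagnosis_date, d$coverage_start_date)
  invalid_death <- !is.na(d$death_date) & d$death_date < d$diagnosis_date

  reason <- dplyr::case_when(
    d$site_code %!in% keep_sites ~ "site_not_eligible",
    age < min_age ~ "age<18",
    coverage < min_coverage_days ~ "coverage<2y",
    invalid_death ~ "invalid_death_date",
    d$death_certificate_only ~ "death_certificate_only",
    d$prior_malignancy ~ "prior_malignancy",
    TRUE ~ NA_character_
  )
  ledger <- tibble::tibble(person_id = d$person_id, reason = reason) |>
    dplyr::filter(!is.na(reason))
  rule_order <- c("site_not_eligible", "age<18", "coverage<2y",
                  "invalid_death_date", "death_certificate_only",
                  "prior_malignancy")
  counts <- setNames(
    vapply(rule_order, function(r) sum(ledger$reason == r), integer(1)),
    rule_order
  )
  list(
    included = d$person_id[is.na(reason)],
    ledger = ledger,
    counts = counts
  )
}

#' Classify severe psychiatric illness exposure for one person
#'
#' Hierarchical algorithm over mental-health encounters in the exposure window
#' (5 years to 6 months before diagnosis, both endpoints inclusive):
#' `inpatient` if at least one hospitalization carries an eligible SPI
#' diagnosis code; otherwise `outpatient` if at least two emergency-department
#' visits or psychiatrist claims carry an eligible code; otherwise
#' `inconclusive` if any mental-health-coded encounter sits in the window
#' (single qualifying visit, family-physician-only care, or non-SPI
#' mental-health codes) — such persons are excluded from analysis; otherwise
#' `none`.
#'
#' @param encounters Encounter rows for one person (a `person_id` filter is
#'   applied if the table has several and `person_id` is given).
#' @param diagnosis_date The person's cancer diagnosis date.
#' @param dictionary Code dictionary (see [default_code_dictionary()]).
#' @param person_id Optional person id to filter `encounters` by.
#' @param distinct_dates If `TRUE`, the two qualifying outpatient visits must
#'   fall on distinct calendar dates; by default distinct encounter rows count
#'   even on the same day.
#' @return A list with `label` (one of none/outpatient/inpatient/inconclusive)
#'   and `qualifying_encounter_ids`.
#' @export
classify_spi <- function(encounters, diagnosis_date,
                         dictionary = default_code_dictionary(),
                         person_id = NULL, distinct_dates = FALSE) {
  if (!is.null(person_id)) {
    encounters <- encounters[encounters$person_id == person_id, ]
  }
  days_pre <- days_between(diagnosis_date, encounters$date)
  in_win <- days_pre >= SPI_WINDOW_MIN & days_pre <= SPI_WINDOW_MAX
  mh <- in_win & encounters$diagnosis_code %in% dictionary$mental_health_codes
  eligible <- in_win & encounters$diagnosis_code %in% dictionary$spi_codes

  ip <- eligible & encounters$setting == "hospitalization"
  if (any(ip)) {
    return(list(label = "inpatient",
                qualifying_encounter_ids = encounter_ids(encounters)[ip]))
  }
  op <- eligible & (encounters$setting == "emergency" |
                      (encounters$setting == "physician_claim" &
                         encounters$provider_specialty == "psychiatrist"))
  n_op <- if (distinct_dates) length(unique(encounters$date[op])) else sum(op)
  if (n_op >= 2L) {
    return(list(label = "outpatient",
                qualifying_encounter_ids = encounter_ids(encounters)[op]))
  }
  if (any(mh)) {
    return(list(label = "inconclusive",
                qualifying_encounter_ids = encounter_ids(encounters)[mh]))
  }
  list(label = "none", qualifying_encounter_ids = character(0))
}

encounter_ids <- function(encounters) {
  encounters$encounter_id %||% rep(NA_character_, nrow(encounters))
}

# Vectorized SPI classification for a whole cohort; identical logic to
# classify_spi() row-set-wise (tested for equivalence against it).
classify_spi_all <- function(encounters, cancers,
                             dictionary = default_code_dictionary(),
                             distinct_dates = FALSE) {
  e <- dplyr::inner_join(
    encounters,
    dplyr::select(cancers, person_id, diagnosis_date),
    by = "person_id"
  )
  e$days_pre <- days_between(e$diagnosis_date, e$date)
  e <- e[e$days_pre >= SPI_WINDOW_MIN & e$days_pre <= SPI_WINDOW_MAX &
           e$diagnosis_code %in% dictionary$mental_health_codes, ]
  if (nrow(e)) {
    e$eligible <- e$diagnosis_code %in% dictionary$spi_codes
    e$ip <- e$eligible & e$setting == "hospitalization"
    e$op <- e$eligible & (e$setting == "emergency" |
                            (e$setting == "physician_claim" &
                               e$provider_specialty == "psychiatrist"))
    agg <- e |>
      dplyr::group_by(person_id) |>
      dplyr::summarise(
        any_ip = any(ip),
        n_op = if (distinct_dates) dplyr::n_distinct(date[op]) else sum(op),
        .groups = "drop"
      )
  } else {
    agg <- tibble::tibble(person_id = character(0), any_ip = logical(0),
                          n_op = integer(0))
  }
  out <- dplyr::left_join(dplyr::select(cancers, person_id), agg,
                          by = "person_id")
  dplyr::mutate(out, spi = dplyr::case_when(
    is.na(any_ip) ~ "none",
    any_ip ~ "inpatient",
    n_op >= 2 ~ "outpatient",
    TRUE ~ "inconclusive"
  )) |>
    dplyr::select(person_id, spi)
}

#' Derive analysis covariates for included persons
#'
#' Continuous age at diagnosis plus the age band used in descriptive tables
#' (≤50, 51–60, 61–70, 71–80, >80), the comorbidity dichotomy (Elixhauser-type
#' score ≥ 4 = more comorbid), the rurality dichotomy (rurality index ≥ 45 =
#' rural), diagnosis year, and the neighborhood income quintile passed
#' through. Missing inputs propagate as missing; nothing is imputed.
#'
#' @param persons,cancers Person and cancer registry rows (joined on
#'   `person_id`).
#' @return A tibble of person-level covariates.
#' @export
derive_covariates <- function(persons, cancers) {
  d <- dplyr::inner_join(persons, cancers, by = "person_id")
  age <- days_between(d$diagnosis_date, d$birth_date) / 365.25
  age_int <- floor(age + 1e-9)
  tibble::tibble(
    person_id = d$person_id,
    age = age,
    age_band = dplyr::case_when(
      age_int <= 50 ~ "<=50",
      age_int <= 60 ~ "51-60",
      age_int <= 70 ~ "61-70",
      age_int <= 80 ~ "71-80",
      TRUE ~ ">80"
    ),
    sex = d$sex,
    more_comorbid = !is.na(d$comorbidity_score) & d$comorbidity_score >= 4,
    rural = !is.na(d$rio_score) & d$rio_score >= 45,
    income_quintile = d$income_quintile,
    year = as.integer(format(d$diagnosis_date, "%Y")),
    histology = d$histology,
    stage = d$stage
  )
}

#' Build the analysis cohort
#'
#' Runs [apply_exclusions()], classifies SPI exposure for the remaining
#' persons, excludes inconclusive mental-health histories (appended to the
#' ledger), and attaches covariates from [derive_covariates()].
#'
#' @inheritParams apply_exclusions
#' @param encounters Encounter table.
#' @param dictionary Code dictionary.
#' @param distinct_dates Passed to the SPI classifier.
#' @return A list: `cohort` (one row per included person with `spi` label and
#'   covariates), `ledger`, `counts`.
#' @export
build_cohort <- function(persons, encounters, cancers,
                         dictionary = default_code_dictionary(),
                         distinct_dates = FALSE) {
  excl <- apply_exclusions(persons, cancers)
  keep <- cancers$person_id %in% excl$included
  spi <- classify_spi_all(encounters, cancers[keep, ], dictionary,
                          distinct_dates = distinct_dates)
  inconclusive <- spi$person_id[spi$spi == "inconclusive"]
  ledger <- dplyr::bind_rows(
    excl$ledger,
    tibble::tibble(person_id = inconclusive,
                   reason = "inconclusive_mh_history")
  )
  included <- setdiff(excl$included, inconclusive)
  cov <- derive_covariates(persons[persons$person_id %in% included, ],
                           cancers[cancers$person_id %in% included, ])
  cohort <- dplyr::inner_join(
    dplyr::filter(spi, person_id %in% included), cov, by = "person_id") |>
    dplyr::left_join(
      dplyr::select(cancers, person_id, diagnosis_date), by = "person_id")
  counts <- c(excl$counts,
              inconclusive_mh_history = length(inconclusive))
  list(cohort = cohort, ledger = ledger, counts = counts)
}
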