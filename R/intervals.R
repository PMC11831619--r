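# Empirical diagnostic-interval algorithm:
#   1. select cancer-related encounter-type groups by frequency ratio
#      (pre-diagnostic vs control period rates),
#   2. derive a per-group lookback window from a control chart on the
#      cohort-level weekly encounter series,
#   3. resolve each person's first contact inside the selected windows, with a
#      365-day referral lookback when the first contact is a procedure,
#   4. interval = days from the resolved start date to diagnosis.

PRE_WINDOW <- c(0L, 90L)      # 0-3 months before diagnosis, in 30-day months
CONTROL_WINDOW <- c(720L, 810L)  # 24-27 months before diagnosis

#' Frequency-ratio selection of cancer-related encounter types
#'
#' Pools, over persons with at least 27 months (810 days) of pre-diagnosis
#' observability, the event rate of each encounter-type group in the 0–3
#' month pre-diagnostic window (days 0–90 before diagnosis) and in the 24–27
#' month control window (days 720–810), and flags groups whose pre-diagnostic
#' rate is at least `threshold` (default 1.2, i.e. 20% more frequent) times
#' the control rate. Groups with zero control events are selected when they
#' have at least `min_pre_events` pre-diagnostic events; a +0.5 continuity
#' correction is used for the reported ratio when the control count is zero
#' but the evidence threshold is not met.
#'
#' @param encounters,cancers Encounter and cancer tables.
#' @param dictionary Code dictionary providing the code-to-group mapping.
#' @param persons Optional person table; when given, persons whose coverage
#'   starts later than 810 days before diagnosis are dropped from rate
#'   estimation.
#' @param threshold Selection threshold on the frequency ratio.
#' @param min_pre_events Minimum pre-diagnostic events for the zero-control
#'   selection rule.
#' @param unit `"count"` pools encounter counts (default); `"person"` pools
#'   person-level any-encounter indicators per window.
#' @return A tibble (one row per group): rates per person-month in each
#'   window, `frequency_ratio`, `selected`, and an unset `lookback_days`
#'   column to be filled by [fit_lookback()].
#' @export
compute_frequency_ratios <- function(encounters, cancers,
                                     dictionary = default_code_dictionary(),
                                     persons = NULL, threshold = 1.2,
                                     min_pre_events = 5L,
                                     unit = c("count", "person")) {
  unit <- match.arg(unit)
  if (nrow(cancers) == 0L) data_error("Empty cohort: no cancer rows")
  if (!is.null(persons)) {
    obs <- dplyr::inner_join(persons, cancers, by = "person_id")
    ok <- days_between(obs$diagnosis_date, obs$coverage_start_date) >=
      CONTROL_WINDOW[2]
    cancers <- cancers[cancers$person_id %in% obs$person_id[ok], ]
    if (nrow(cancers) == 0L) {
      data_error("Empty cohort: no person has 27 months of pre-diagnosis observability")
    }
  }
  n_persons <- nrow(cancers)
  e <- dplyr::inner_join(
    encounters, dplyr::select(cancers, person_id, diagnosis_date),
    by = "person_id"
  )
  e$group_label <- unname(dictionary$encounter_groups[e$diagnosis_code])
  e <- e[!is.na(e$group_label), ]
  e$days_pre <- days_between(e$diagnosis_date, e$date)

  window_events <- function(lo, hi) {
    w <- e[e$days_pre >= lo & e$days_pre <= hi, ]
    if (unit == "person") {
      w <- dplyr::distinct(w, person_id, group_label)
    }
    dplyr::count(w, group_label, name = "events")
  }
  groups <- sort(unique(unname(dictionary$encounter_groups)))
  months_exposure <- n_persons * (PRE_WINDOW[2] - PRE_WINDOW[1] + 1L) /
    DAYS_PER_MONTH

  pre <- window_events(PRE_WINDOW[1], PRE_WINDOW[2])
  ctl <- window_events(CONTROL_WINDOW[1], CONTROL_WINDOW[2])
  out <- tibble::tibble(group_label = groups) |>
    dplyr::left_join(dplyr::rename(pre, n_pre_events = events), by = "group_label") |>
    dplyr::left_join(dplyr::rename(ctl, n_control_events = events), by = "group_label") |>
    tidyr::replace_na(list(n_pre_events = 0L, n_control_events = 0L))
  out$rate_prediagnostic <- out$n_pre_events / months_exposure
  out$rate_control <- out$n_control_events / months_exposure
  out$frequency_ratio <- ifelse(
    out$n_control_events > 0,
    out$n_pre_events / out$n_control_events,
    (out$n_pre_events + 0.5) / 0.5
  )
  out$selected <- ifelse(
    out$n_control_events > 0,
    out$frequency_ratio >= threshold,
    out$n_pre_events >= min_pre_events
  )
  out$lookback_days <- NA_integer_
  out
}

#' Cohort-level weekly pre-diagnosis encounter series
#'
#' Week `w` counts encounters dated `7(w-1)` to `7w - 1` days before
#' diagnosis (week 1 includes the diagnosis day), pooled over the cohort.
#'
#' @inheritParams compute_frequency_ratios
#' @param group Encounter-type group label.
#' @param weeks Integer vector of week indices (default 1:104).
#' @return Tibble with `week` and `count`.
#' @export
weekly_encounter_series <- function(group, encounters, cancers,
                                    dictionary = default_code_dictionary(),
                                    weeks = 1:104) {
  e <- dplyr::inner_join(
    encounters, dplyr::select(cancers, person_id, diagnosis_date),
    by = "person_id"
  )
  e$group_label <- unname(dictionary$encounter_groups[e$diagnosis_code])
  e <- e[!is.na(e$group_label) & e$group_label == group, ]
  e$days_pre <- days_between(e$diagnosis_date, e$date)
  e <- e[e$days_pre >= 0L, ]
  e$week <- e$days_pre %/% 7L + 1L
  counts <- dplyr::count(e[e$week %in% weeks, ], week, name = "count")
  tibble::tibble(week = as.integer(weeks)) |>
    dplyr::left_join(counts, by = "week") |>
    tidyr::replace_na(list(count = 0L))
}

#' Control-chart lookback for a selected encounter group
#'
#' Builds the cohort weekly encounter-count series for weeks 1–104 before
#' diagnosis, sets an upper control limit at mean + 3 SD of the counts over
#' the control weeks (a Shewhart-style individuals chart; default weeks
#' 96–104), and returns `7 * w` where `w` is the last week of the unbroken
#' run of elevated weeks ending at diagnosis — i.e. every week from `w` down
#' to 1 exceeds the limit. Isolated elevated weeks beyond the run are ignored.
#' If week 1 itself is not elevated the lookback defaults to
#' `default_lookback` (90 days). The result is capped at `cap` (730 days) so
#' the lookback can never reach into the control period.
#'
#' @inheritParams weekly_encounter_series
#' @param persons Optional person table; when given, only persons observable
#'   over the full chart horizon (coverage starting at least `7 * max(weeks)`
#'   days before diagnosis) contribute to the series.
#' @param control_weeks Weeks defining the control limits (at least 8).
#' @param default_lookback Fallback lookback in days when no elevation is
#'   detected.
#' @param cap Maximum lookback in days.
#' @return Lookback length in days (integer).
#' @export
fit_lookback <- function(group, encounters, cancers,
                         dictionary = default_code_dictionary(),
                         persons = NULL, weeks = 1:104,
                         control_weeks = 96:104,
                         default_lookback = 90L, cap = 730L) {
  if (length(control_weeks) < 8L) {
    data_error("insufficient control period: need at least 8 control weeks")
  }
  if (!all(control_weeks %in% weeks)) {
    data_error("control_weeks must be a subset of the chart weeks")
  }
  if (!is.null(persons)) {
    obs <- dplyr::inner_join(persons, cancers, by = "person_id")
    ok <- days_between(obs$diagnosis_date, obs$coverage_start_date) >=
      7L * max(weeks)
    cancers <- cancers[cancers$person_id %in% obs$person_id[ok], ]
    if (nrow(cancers) == 0L) {
      data_error("insufficient control period: no person observable over the chart horizon")
    }
  }
  series <- weekly_encounter_series(group, encounters, cancers, dictionary,
                                    weeks = weeks)
  ctl <- series$count[series$week %in% control_weeks]
  ucl <- mean(ctl) + 3 * stats::sd(ctl)
  elevated <- series$count > ucl
  # longest unbroken elevated run starting at week 1
  run <- cumprod(elevated[order(series$week)])
  w <- sum(run)
  if (w == 0L) return(as.integer(default_lookback))
  min(as.integer(7L * w), as.integer(cap))
}

#' Fit lookbacks for every selected group in a profile table
#'
#' Convenience wrapper applying [fit_lookback()] to each selected group and
#' filling the profile table's `lookback_days` column.
#'
#' @param profiles Profile table from [compute_frequency_ratios()].
#' @inheritParams fit_lookback
#' @param ... Passed on to [fit_lookback()].
#' @return `profiles` with `lookback_days` filled for selected groups.
#' @export
fit_lookbacks <- function(profiles, encounters, cancers,
                          dictionary = default_code_dictionary(),
                          persons = NULL, ...) {
  sel <- which(profiles$selected)
  for (i in sel) {
    profiles$lookback_days[i] <- fit_lookback(
      profiles$group_label[i], encounters, cancers, dictionary,
      persons = persons, ...)
  }
  profiles
}

#' Resolve first contact and diagnostic interval for a whole cohort
#'
#' For each person, candidate encounters are those whose encounter-type group
#' is selected and whose date falls within that group's lookback window
#' before diagnosis (both endpoints inclusive). The first contact is the
#' earliest candidate (ties on the same day resolved in favor of
#' non-procedure encounters, then by encounter id). If the first contact is a
#' procedure with a recorded referring provider, the start date moves back to
#' the latest visit with that provider in the preceding 365 days, when one
#' exists. Persons with no candidate encounter are flagged non-identifiable
#' (`identifiable = FALSE`) and are excluded upstream.
#'
#' @inheritParams compute_frequency_ratios
#' @param profiles Profile table from [compute_frequency_ratios()] with
#'   `lookback_days` filled for selected groups (see [fit_lookback()]).
#' @param referral_lookback_days Window for the referring-provider search.
#' @return A tibble, one row per person in `cancers`: `first_contact_date`,
#'   `resolved_start_date`, `interval_days`, `used_referral_lookback`,
#'   `identifiable`.
#' @export
compute_intervals <- function(encounters, cancers, profiles,
                              dictionary = default_code_dictionary(),
                              referral_lookback_days = 365L) {
  encounters <- normalize_encounters(encounters)
  sel <- profiles[profiles$selected & !is.na(profiles$lookback_days),
                  c("group_label", "lookback_days")]
  e <- dplyr::inner_join(
    encounters, dplyr::select(cancers, person_id, diagnosis_date),
    by = "person_id"
  )
  e$group_label <- unname(dictionary$encounter_groups[e$diagnosis_code])
  cand <- dplyr::inner_join(e, sel, by = "group_label")
  cand$days_pre <- days_between(cand$diagnosis_date, cand$date)
  cand <- cand[cand$days_pre >= 0L & cand$days_pre <= cand$lookback_days, ]

  fc <- cand |>
    dplyr::arrange(person_id, date, is_procedure, encounter_id) |>
    dplyr::distinct(person_id, .keep_all = TRUE) |>
    dplyr::select(person_id, diagnosis_date,
                  first_contact_date = date,
                  fc_is_procedure = is_procedure,
                  fc_referrer = referring_provider_id)

  # 365-day referral lookback for procedure first contacts
  need_ref <- fc[fc$fc_is_procedure & !is.na(fc$fc_referrer), ]
  ref_dates <- tibble::tibble(person_id = character(0),
                              referral_date = as.Date(character(0)))
  if (nrow(need_ref)) {
    prior <- dplyr::inner_join(
      dplyr::select(encounters, person_id, provider_id, date),
      dplyr::select(need_ref, person_id, fc_referrer, first_contact_date),
      by = "person_id", relationship = "many-to-many"
    )
    prior <- prior[!is.na(prior$provider_id) &
                     prior$provider_id == prior$fc_referrer &
                     prior$date < prior$first_contact_date &
                     prior$date >= prior$first_contact_date - referral_lookback_days, ]
    if (nrow(prior)) {
      ref_dates <- prior |>
        dplyr::group_by(person_id) |>
        dplyr::summarise(referral_date = max(date), .groups = "drop")
    }
  }
  fc <- dplyr::left_join(fc, ref_dates, by = "person_id")
  fc$used_referral_lookback <- !is.na(fc$referral_date)
  fc$resolved_start_date <- dplyr::if_else(fc$used_referral_lookback,
                                           fc$referral_date,
                                           fc$first_contact_date)
  fc$interval_days <- days_between(fc$diagnosis_date, fc$resolved_start_date)

  out <- dplyr::left_join(dplyr::select(cancers, person_id, diagnosis_date),
                          dplyr::select(fc, person_id, first_contact_date,
                                        resolved_start_date, interval_days,
                                        used_referral_lookback),
                          by = "person_id")
  out$identifiable <- !is.na(out$first_contact_date)
  out$used_referral_lookback[!out$identifiable] <- FALSE
  out
}

#' Resolve first contact for a single person
#'
#' Single-person wrapper around [compute_intervals()]; returns the
#' diagnostic-interval row for one encounter history, or a non-identifiable
#' row when no candidate encounter exists.
#'
#' @param person_encounters Encounter rows for one person.
#' @param profiles Fitted profile table (selected groups with lookbacks).
#' @param diagnosis_date Diagnosis date.
#' @inheritParams compute_intervals
#' @return A one-row tibble as in [compute_intervals()].
#' @export
resolve_first_contact <- function(person_encounters, profiles, diagnosis_date,
                                  dictionary = default_code_dictionary(),
                                  referral_lookback_days = 365L) {
  pid <- unique(person_encounters$person_id)
  if (length(pid) > 1L) data_error("person_encounters spans several persons")
  if (length(pid) == 0L) pid <- "anonymous"
  cancers <- tibble::tibble(person_id = pid, diagnosis_date = diagnosis_date)
  compute_intervals(person_encounters, cancers, profiles, dictionary,
                    referral_lookback_days)
}
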