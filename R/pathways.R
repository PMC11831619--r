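# Diagnostic-pathway classification: symptom status at diagnosis, emergent
# status, and — for symptomatic persons — which procedures the workup used,
# for four procedure classes crossed with the emergent flag (eight pathways).

#' Classify symptom status at diagnosis for one person
#'
#' A person is on the no-symptom-recorded pathway (a surrogate for
#' screen-initiated detection) iff, on the resolved first contact date, they
#' received a guaiac fecal occult blood test or a lower-GI endoscopy outside
#' an emergency setting, no encounter on that date carries a symptom code,
#' and no earlier encounter in the record carries a symptom code. Everyone
#' else is symptomatic. The prior-symptom scan is unbounded (the full
#' available record), an interpretive choice discussed in the methods
#' vignette.
#'
#' @param person_encounters Encounter rows for one person.
#' @param interval A one-row diagnostic-interval result (from
#'   [resolve_first_contact()] or one row of [compute_intervals()]).
#' @return `"no_symptom_recorded"` or `"symptomatic"`.
#' @export
classify_symptom_status <- function(person_encounters, interval) {
  if (!isTRUE(interval$identifiable %||% TRUE) ||
      is.na(interval$first_contact_date)) {
    return("symptomatic")
  }
  e <- normalize_encounters(person_encounters)
  fc <- interval$first_contact_date
  on_fc <- e$date == fc
  screen_test <- on_fc & e$procedure_kind %in% c("gFOBT", "lower_GI_scope") &
    e$setting != "emergency"
  symptom_on_fc <- any(on_fc & e$is_symptom_code)
  symptom_before <- any(e$date < fc & e$is_symptom_code)
  if (any(screen_test) && !symptom_on_fc && !symptom_before) {
    "no_symptom_recorded"
  } else {
    "symptomatic"
  }
}

#' Emergent diagnosis flag for one person
#'
#' `TRUE` iff any emergency-department encounter falls exactly on the
#' diagnosis date.
#'
#' @param person_encounters Encounter rows for one person.
#' @param diagnosis_date Diagnosis date.
#' @return Logical flag.
#' @export
classify_emergent <- function(person_encounters, diagnosis_date) {
  any(person_encounters$setting == "emergency" &
        person_encounters$date == diagnosis_date)
}

#' Assign the diagnostic pathway for one person
#'
#' For symptomatic persons, scans procedures dated between the resolved start
#' date and the diagnosis date (both inclusive): colonoscopy (identified by
#' the dictionary's colonoscopy procedure codes) and imaging
#' (`procedure_kind == "imaging"`) define four procedure classes —
#' colonoscopy only, colonoscopy plus imaging, imaging only, neither —
#' crossed with the emergent flag for eight pathways. For persons on the
#' no-symptom-recorded pathway the procedure class is undefined (`NA`).
#'
#' @param person_encounters Encounter rows for one person.
#' @param interval One-row diagnostic-interval result.
#' @param symptom_status From [classify_symptom_status()].
#' @param emergent From [classify_emergent()].
#' @param dictionary Code dictionary.
#' @return A list with `symptom_status`, `emergent`, `procedure_class`, and
#'   the combined `pathway` label.
#' @export
assign_pathway <- function(person_encounters, interval, symptom_status,
                           emergent,
                           dictionary = default_code_dictionary()) {
  if (symptom_status == "no_symptom_recorded") {
    return(list(symptom_status = symptom_status, emergent = emergent,
                procedure_class = NA_character_,
                pathway = "no_symptom_recorded"))
  }
  e <- normalize_encounters(person_encounters)
  in_win <- e$date >= interval$resolved_start_date &
    e$date <= (interval$resolved_start_date + interval$interval_days)
  proc <- e$is_procedure & in_win
  has_col <- any(proc & e$diagnosis_code %in% dictionary$colonoscopy_codes)
  has_img <- any(proc & e$procedure_kind == "imaging")
  procedure_class <- if (has_col && has_img) "colonoscopy_plus_imaging"
    else if (has_col) "colonoscopy_only"
    else if (has_img) "imaging_only"
    else "neither"
  list(
    symptom_status = symptom_status, emergent = emergent,
    procedure_class = procedure_class,
    pathway = paste0(procedure_class, if (emergent) "+ED" else "+no_ED")
  )
}

#' Classify symptom status, emergent status and pathway for a cohort
#'
#' Vectorized application of [classify_symptom_status()],
#' [classify_emergent()] and [assign_pathway()] over every identifiable
#' person in an interval table.
#'
#' @param encounters Encounter table.
#' @param cancers Cancer table (for diagnosis dates).
#' @param intervals Interval table from [compute_intervals()].
#' @param dictionary Code dictionary.
#' @return A tibble: `person_id`, `symptom_status`, `emergent`,
#'   `procedure_class`, `pathway`.
#' @export
classify_pathways <- function(encounters, cancers, intervals,
                              dictionary = default_code_dictionary()) {
  e <- normalize_encounters(encounters)
  iv <- dplyr::inner_join(
    intervals[intervals$identifiable, ],
    dplyr::select(cancers, person_id, dx = diagnosis_date),
    by = "person_id"
  )
  ee <- dplyr::inner_join(
    dplyr::select(e, person_id, date, setting, diagnosis_code, is_procedure,
                  procedure_kind, is_symptom_code),
    dplyr::select(iv, person_id, first_contact_date, resolved_start_date, dx),
    by = "person_id"
  )
  agg <- ee |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(
      screen_test_on_fc = any(date == first_contact_date &
                                procedure_kind %in% c("gFOBT", "lower_GI_scope") &
                                setting != "emergency"),
      symptom_on_or_before_fc = any(date <= first_contact_date &
                                      is_symptom_code),
      emergent = any(setting == "emergency" & date == dx),
      has_col = any(is_procedure & date >= resolved_start_date & date <= dx &
                      diagnosis_code %in% dictionary$colonoscopy_codes),
      has_img = any(is_procedure & date >= resolved_start_date & date <= dx &
                      procedure_kind == "imaging"),
      .groups = "drop"
    )
  out <- dplyr::left_join(dplyr::select(iv, person_id), agg, by = "person_id") |>
    tidyr::replace_na(list(screen_test_on_fc = FALSE,
                           symptom_on_or_before_fc = FALSE,
                           emergent = FALSE, has_col = FALSE, has_img = FALSE))
  out$symptom_status <- ifelse(
    out$screen_test_on_fc & !out$symptom_on_or_before_fc,
    "no_symptom_recorded", "symptomatic"
  )
  out$procedure_class <- dplyr::case_when(
    out$symptom_status == "no_symptom_recorded" ~ NA_character_,
    out$has_col & out$has_img ~ "colonoscopy_plus_imaging",
    out$has_col ~ "colonoscopy_only",
    out$has_img ~ "imaging_only",
    TRUE ~ "neither"
  )
  out$pathway <- ifelse(
    out$symptom_status == "no_symptom_recorded", "no_symptom_recorded",
    paste0(out$procedure_class, ifelse(out$emergent, "+ED", "+no_ED"))
  )
  dplyr::select(out, person_id, symptom_status, emergent, procedure_class,
                pathway)
}
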