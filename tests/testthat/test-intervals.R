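# A two-group dictionary for constructed frequency-ratio fixtures.
mini_dict <- function() {
  list(
    encounter_groups = c(A1 = "grpA", B1 = "grpB", C1 = "grpC", D1 = "grpD"),
    spi_codes = character(0), mental_health_codes = character(0),
    colonoscopy_codes = character(0)
  )
}

mini_cancers <- function(persons = "P1", dx = DX) {
  tibble::tibble(person_id = persons, diagnosis_date = dx)
}

test_that("frequency-ratio selection applies the 20% rule and the zero-control rule", {
  # grpA: 12 pre vs 10 control (ratio 1.2, selected); grpB: 10 vs 10 (1.0);
  # grpC: 5 pre, 0 control (selected by evidence rule); grpD: 2 pre, 0 control
  e <- dplyr::bind_rows(
    enc(rep(10, 12), code = "A1"), enc(rep(750, 10), code = "A1"),
    enc(rep(20, 10), code = "B1"), enc(rep(760, 10), code = "B1"),
    enc(rep(30, 5), code = "C1"),
    enc(rep(40, 2), code = "D1")
  )
  prof <- compute_frequency_ratios(e, mini_cancers(), mini_dict())
  prof <- prof[order(prof$group_label), ]
  expect_equal(prof$frequency_ratio[prof$group_label == "grpA"], 1.2)
  expect_true(prof$selected[prof$group_label == "grpA"])
  expect_equal(prof$frequency_ratio[prof$group_label == "grpB"], 1.0)
  expect_false(prof$selected[prof$group_label == "grpB"])
  expect_true(prof$selected[prof$group_label == "grpC"])
  expect_false(prof$selected[prof$group_label == "grpD"])
  # continuity-corrected ratio reported for the zero-control groups
  expect_equal(prof$frequency_ratio[prof$group_label == "grpD"], 2.5 / 0.5)
  # empty cohort errors
  expect_error(compute_frequency_ratios(e, mini_cancers()[0, ], mini_dict()),
               "Empty cohort", class = "dxinterval_data_error")
})

test_that("rates are per person-month and persons lacking 27-month observability are dropped", {
  e <- enc(rep(10, 30), code = "A1")
  persons <- tibble::tibble(
    person_id = c("P1", "P2"),
    coverage_start_date = c(DX - 2000, DX - 400)
  )
  prof <- compute_frequency_ratios(e, mini_cancers(c("P1", "P2")),
                                   mini_dict(), persons = persons)
  # only P1 is observable: exposure = 1 person * 91 days / 30
  expect_equal(prof$rate_prediagnostic[prof$group_label == "grpA"],
               30 / (91 / 30))
  # person-level indicator mode counts each person at most once per window
  prof2 <- compute_frequency_ratios(e, mini_cancers(), mini_dict(),
                                    unit = "person")
  expect_equal(prof2$n_pre_events[prof2$group_label == "grpA"], 1L)
})

test_that("simulated signal groups are selected and a null group is not", {
  cfg <- quick_config(
    n = 1200, seed = 17,
    signal_rate_multipliers = c(gi_endoscopy = 2, abdominal_imaging = 2,
                                gi_physician = 1, primary_care = 1,
                                other_care = 1, mental_health = 1),
    base_encounter_rates = c(gi_endoscopy = 0.02, abdominal_imaging = 0.02,
                             gi_physician = 0.001, primary_care = 0.05,
                             other_care = 0.03, mental_health = 0)
  )
  tabs <- simulate_claims(cfg)
  prof <- compute_frequency_ratios(tabs$encounters, tabs$cancers,
                                   cfg$dictionary, persons = tabs$persons)
  expect_true(prof$selected[prof$group_label == "gi_endoscopy"])
  expect_true(prof$selected[prof$group_label == "abdominal_imaging"])
  expect_false(prof$selected[prof$group_label == "primary_care"])
  expect_false(prof$selected[prof$group_label == "other_care"])
})

# Build an encounter stream realizing an exact weekly count series: week w
# (days 7(w-1)..7w-1 before diagnosis) gets `counts[w]` encounters.
series_encounters <- function(counts, code = "A1") {
  days <- rep(7L * (seq_along(counts) - 1L), counts)
  enc(days, code = code)
}

test_that("the control-chart lookback follows the run-ending-at-diagnosis rule", {
  # flat series: no exceedance -> default 90 days
  flat <- series_encounters(rep(5L, 104))
  expect_equal(fit_lookback("grpA", flat, mini_cancers(), mini_dict()), 90L)
  # elevation in weeks 1-20 plus an isolated spike at week 40 -> 140 days
  counts <- rep(5L, 104)
  counts[1:20] <- 12L
  counts[40] <- 12L
  run <- series_encounters(counts)
  expect_equal(fit_lookback("grpA", run, mini_cancers(), mini_dict()), 140L)
  # elevation everywhere is capped at 730
  all_up <- series_encounters(c(rep(12L, 95), rep(5L, 9)))
  expect_equal(fit_lookback("grpA", all_up, mini_cancers(), mini_dict()), 665L)
  # a run longer than the cap is truncated so the control period stays clean
  long_run <- series_encounters(c(rep(12L, 110), rep(5L, 9)))
  expect_equal(fit_lookback("grpA", long_run, mini_cancers(), mini_dict(),
                            weeks = 1:119, control_weeks = 111:119), 730L)
  # too few control weeks is an error
  expect_error(fit_lookback("grpA", flat, mini_cancers(), mini_dict(),
                            control_weeks = 96:102),
               "insufficient control period", class = "dxinterval_data_error")
})

test_that("an injected 26-week onset is recovered by the lookback fit", {
  cfg <- sim_config(
    n_persons = 5000, seed = 61,
    spi_mix = c(none = 1, outpatient = 0, inpatient = 0, inconclusive = 0),
    true_interval_days = list(
      none = list(family = "fixed", days = 182),
      outpatient = list(family = "fixed", days = 182),
      inpatient = list(family = "fixed", days = 182),
      inconclusive = list(family = "fixed", days = 182)
    ),
    no_symptom_fraction = c(none = 0, outpatient = 0, inpatient = 0,
                            inconclusive = 0),
    base_encounter_rates = c(gi_endoscopy = 0, abdominal_imaging = 0,
                             gi_physician = 0.001, primary_care = 0,
                             other_care = 0, mental_health = 0),
    signal_rate_multipliers = c(gi_endoscopy = 1, abdominal_imaging = 1,
                                gi_physician = 20, primary_care = 1,
                                other_care = 1, mental_health = 1),
    procedure_probs = c(colonoscopy = 0, imaging = 0),
    emergent_fraction = 0,
    exclusion_fractions = c(short_coverage = 0, under_18 = 0,
                            invalid_death = 0, death_certificate_only = 0,
                            prior_malignancy = 0, other_site = 0)
  )
  tabs <- simulate_claims(cfg)
  lb <- fit_lookback("gi_physician", tabs$encounters, tabs$cancers,
                     cfg$dictionary, persons = tabs$persons)
  expect_gte(lb, 182 - 14)
  expect_lte(lb, 182 + 14)
})

test_that("first-contact resolution handles the documented edge cases", {
  profiles <- make_profiles(c("gi_physician", "gi_endoscopy"), c(90, 200))
  # single candidate on the diagnosis date: interval 0
  r <- resolve_first_contact(enc(0, code = "GI_SYMPT"), profiles, DX)
  expect_equal(r$interval_days, 0L)
  expect_true(r$identifiable)
  # a colonoscopy first contact with a referring visit 30 days earlier
  # extends the interval by 30 days via the referral lookback
  h <- dplyr::bind_rows(
    enc(60, code = "ENDO_COL", procedure = TRUE, kind = "lower_GI_scope",
        referrer = "GP1"),
    enc(90, code = "PC_VISIT", provider = "GP1")
  )
  r <- resolve_first_contact(h, profiles, DX)
  expect_equal(as.integer(DX - r$first_contact_date), 60L)
  expect_equal(r$interval_days, 90L)
  expect_true(r$used_referral_lookback)
  # ... but only within 365 days
  h2 <- dplyr::bind_rows(
    enc(60, code = "ENDO_COL", procedure = TRUE, kind = "lower_GI_scope",
        referrer = "GP1"),
    enc(60 + 366, code = "PC_VISIT", provider = "GP1")
  )
  r2 <- resolve_first_contact(h2, profiles, DX)
  expect_false(r2$used_referral_lookback)
  expect_equal(r2$interval_days, 60L)
  # earlier candidate outside its own group's window loses to a later one
  h3 <- dplyr::bind_rows(
    enc(120, code = "GI_SYMPT"),   # gi_physician, window only 90 days
    enc(80, code = "ENDO_FUP")     # gi_endoscopy, within its 200-day window
  )
  r3 <- resolve_first_contact(h3, profiles, DX)
  expect_equal(as.integer(DX - r3$first_contact_date), 80L)
  # no candidates at all: non-identifiable
  r4 <- resolve_first_contact(enc(500, code = "GI_SYMPT"), profiles, DX)
  expect_false(r4$identifiable)
  expect_true(is.na(r4$interval_days))
})

test_that("first-contact resolution matches a brute-force oracle on random fixtures", {
  dict <- default_code_dictionary()
  codes <- c("GI_SYMPT", "GI_VISIT", "ENDO_COL", "ENDO_FUP", "IMG_CT",
             "PC_VISIT", "OTH_VISIT", "MDD")
  set.seed(202)
  n_mismatch <- 0L
  for (rep in 1:200) {
    k <- sample(1:6, 1)
    h <- enc(sample(0:400, k, replace = TRUE),
             code = sample(codes, k, replace = TRUE),
             procedure = FALSE)
    # make some encounters procedures with referrers, add provider visits
    proc <- runif(k) < 0.3
    h$is_procedure <- proc
    h$procedure_kind[proc] <- "lower_GI_scope"
    h$referring_provider_id[proc & runif(k) < 0.7] <- "GPX"
    h$provider_id[runif(k) < 0.4] <- "GPX"
    profiles <- make_profiles(
      c("gi_physician", "gi_endoscopy", "abdominal_imaging"),
      sample(c(30, 90, 180, 365), 3, replace = TRUE),
      selected = c(TRUE, TRUE, runif(1) < 0.5)
    )
    got <- resolve_first_contact(h, profiles, DX)
    want <- fc_oracle(h, profiles, DX)
    if (is.null(want)) {
      if (got$identifiable) n_mismatch <- n_mismatch + 1L
    } else if (!identical(got$interval_days, want$interval_days) ||
               !identical(as.Date(got$first_contact_date),
                          want$first_contact_date) ||
               !identical(got$used_referral_lookback,
                          want$used_referral_lookback)) {
      n_mismatch <- n_mismatch + 1L
    }
  }
  expect_equal(n_mismatch, 0L)
})

test_that("enlarging a lookback never delays the first contact", {
  dict <- default_code_dictionary()
  codes <- c("GI_SYMPT", "GI_VISIT", "ENDO_FUP", "IMG_CT")
  set.seed(303)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    h <- enc(sample(0:500, k, replace = TRUE),
             code = sample(codes, k, replace = TRUE))
    lb <- sample(c(60, 120, 240), 3, replace = TRUE)
    p1 <- make_profiles(c("gi_physician", "gi_endoscopy", "abdominal_imaging"), lb)
    p2 <- p1
    j <- sample(3, 1)
    p2$lookback_days[j] <- p2$lookback_days[j] + sample(c(30, 200), 1)
    r1 <- resolve_first_contact(h, p1, DX)
    r2 <- resolve_first_contact(h, p2, DX)
    if (r1$identifiable) {
      expect_true(r2$identifiable)
      expect_lte(as.numeric(r2$first_contact_date),
                 as.numeric(r1$first_contact_date))
      # without referral resolution in play, intervals are monotone too
      expect_gte(r2$interval_days, r1$interval_days)
    }
  }
})
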