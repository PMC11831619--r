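#' Generate synthetic linked administrative claims tables
#'
#' Produces the four linked tables the analytic chain consumes — a person
#' registry, an encounter stream, a cancer registry — plus a ground-truth table
#' recording, for every person, the true exposure group, true symptom-onset
#' date, true diagnostic-interval length and true diagnostic pathway. All
#' downstream stages (exposure classification, interval construction, pathway
#' classification, quantile regression) can therefore be validated against a
#' known data-generating process.
#'
#' The generating model, briefly: each person receives a diagnosis date and an
#' exposure group drawn from `config$spi_mix`; background encounters arrive as
#' a homogeneous Poisson process per encounter group over the whole coverage
#' window; from the true onset date to diagnosis the cancer-signal groups run
#' at `signal_rate_multipliers` times their base rate (a piecewise-constant
#' inhomogeneous Poisson process with a sharp onset); a presenting encounter is
#' always placed on the onset date (a symptom-coded visit for symptomatic
#' persons, a non-emergent gFOBT or lower-GI endoscopy for persons on the
#' no-symptom-recorded pathway); mental-health encounters are placed inside or
#' outside the exposure window according to the true group; and workup
#' procedures, an optional referral visit, and an optional emergency visit on
#' the diagnosis date realize the true diagnostic pathway.
#'
#' @param config A `dx_config` from [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   `(config, seed)` pairs give identical output.
#' @return A list of four tibbles: `persons`, `encounters`, `cancers`, `truth`.
#'   The `encounters` table carries an `origin` column tagging which part of
#'   the generating process produced each row (background, signal, presenting,
#'   workup, referral, emergent, mental-health); downstream analysis code never
#'   reads it — it exists so tests can check truth consistency.
#' @export
#' @examples
#' tabs <- simulate_claims(sim_config(n_persons = 50, seed = 7))
#' names(tabs)
#' nrow(tabs$persons)
simulate_claims <- function(config = sim_config(), seed = config$seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  n <- as.integer(config$n_persons)
  dict <- config$dictionary
  spi_groups <- c("none", "outpatient", "inpatient", "inconclusive")

  person_id <- sprintf("P%06d", seq_len(n))
  gp_id <- sprintf("GP%05d", sample.int(max(200L, n %/% 20L), n, replace = TRUE))
  spi_group <- sample(spi_groups, n, replace = TRUE, prob = config$spi_mix)

  # --- diagnosis dates and cancer registry -------------------------------
  year <- sample(seq(config$study_years[1], config$study_years[2]), n,
                 replace = TRUE)
  diagnosis_date <- as.Date(sprintf("%d-01-01", year)) +
    (sample.int(365L, n, replace = TRUE) - 1L)

  exf <- config$exclusion_fractions
  site_pool <- c("C18.0", paste0("C18.", 2:9))
  site_code <- sample(site_pool, n, replace = TRUE)
  site_code[runif(n) < exf[["other_site"]]] <- "C18.1"
  histology <- ifelse(runif(n) < 0.971, "adenocarcinoma", "other")
  stage <- sample(c("I", "II", "III", "IV", "unknown"), n, replace = TRUE,
                  prob = c(0.185, 0.251, 0.243, 0.180, 0.141))
  death_certificate_only <- runif(n) < exf[["death_certificate_only"]]
  prior_malignancy <- runif(n) < exf[["prior_malignancy"]]

  # --- demographics ------------------------------------------------------
  age <- sex <- rio_score <- comorbidity_score <- numeric(n)
  income_quintile <- integer(n)
  sex <- character(n)
  for (g in spi_groups) {
    idx <- which(spi_group == g)
    if (!length(idx)) next
    cs <- config$covariate_spec[[g]]
    age[idx] <- pmin(pmax(rnorm(length(idx), cs$age_mean, cs$age_sd), 18.5), 99)
    sex[idx] <- ifelse(runif(length(idx)) < cs$sex_female_p, "female", "male")
    rural <- runif(length(idx)) < cs$rural_p
    rio_score[idx] <- ifelse(rural, runif(length(idx), 45, 100),
                             runif(length(idx), 0, 44.9))
    comorbidity_score[idx] <- ifelse(
      runif(length(idx)) < cs$comorbid_ge4_p,
      4L + rpois(length(idx), 1.2),
      sample(0:3, length(idx), replace = TRUE)
    )
    income_quintile[idx] <- sample.int(5L, length(idx), replace = TRUE,
                                       prob = cs$income_quintile_p)
  }
  under18 <- runif(n) < exf[["under_18"]]
  age[under18] <- runif(sum(under18), 8, 17.9)
  birth_date <- diagnosis_date - round(age * 365.25)

  coverage_start_date <- diagnosis_date - config$coverage_days
  short_coverage <- runif(n) < exf[["short_coverage"]]
  coverage_start_date[short_coverage] <- diagnosis_date[short_coverage] -
    sample(100:729, sum(short_coverage), replace = TRUE)

  invalid_death <- runif(n) < exf[["invalid_death"]]
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  post_death <- !invalid_death & runif(n) < 0.25
  death_date[post_death] <- diagnosis_date[post_death] +
    sample(30:1800, sum(post_death), replace = TRUE)
  death_date[invalid_death] <- diagnosis_date[invalid_death] -
    sample(30:300, sum(invalid_death), replace = TRUE)

  # --- ground truth: pathway and interval --------------------------------
  no_symptom <- runif(n) < config$no_symptom_fraction[spi_group]
  true_interval_days <- integer(n)
  for (g in spi_groups) {
    for (ns in c(TRUE, FALSE)) {
      idx <- which(spi_group == g & no_symptom == ns)
      if (!length(idx)) next
      s <- if (ns) config$true_interval_no_symptom[[g]] else
        config$true_interval_days[[g]]
      true_interval_days[idx] <- switch(
        s$family,
        lognormal = pmax(0L, as.integer(round(
          rlnorm(length(idx), meanlog = log(s$median), sdlog = s$sigma)))),
        fixed = as.integer(round(s$days))
      )
    }
  }
  true_onset_date <- diagnosis_date - true_interval_days
  emergent <- !no_symptom & runif(n) < config$emergent_fraction
  has_col <- !no_symptom & runif(n) < config$procedure_probs[["colonoscopy"]]
  has_img <- !no_symptom & runif(n) < config$procedure_probs[["imaging"]]
  procedure_class <- dplyr::case_when(
    no_symptom ~ NA_character_,
    has_col & has_img ~ "colonoscopy_plus_imaging",
    has_col ~ "colonoscopy_only",
    has_img ~ "imaging_only",
    TRUE ~ "neither"
  )
  true_pathway <- ifelse(
    no_symptom, "no_symptom_recorded",
    paste0(procedure_class, ifelse(emergent, "+ED", "+no_ED"))
  )

  # --- encounter assembly ------------------------------------------------
  pieces <- list()
  blank <- function(k) {
    tibble::tibble(
      person_id = character(k), date = as.Date(integer(k), origin = "1970-01-01"),
      setting = character(k), diagnosis_code = character(k),
      provider_specialty = character(k), provider_id = character(k),
      referring_provider_id = NA_character_,
      is_procedure = logical(k), procedure_kind = rep("none", k),
      is_symptom_code = logical(k), origin = character(k)
    )
  }

  # helper: scatter `counts[i]` uniform dates in [from[i], to[i]] per person
  scatter <- function(counts, from, to) {
    i <- rep.int(seq_along(counts), counts)
    span <- as.integer(to)[i] - as.integer(from)[i]
    dates <- as.Date(as.integer(from)[i] +
                       floor(runif(length(i)) * (span + 1L)),
                     origin = "1970-01-01")
    list(idx = i, date = dates)
  }

  bg_codes <- c(gi_endoscopy = "ENDO_FUP", abdominal_imaging = "IMG_FUP",
                gi_physician = "GI_VISIT", primary_care = "PC_VISIT",
                other_care = "OTH_VISIT")

  # background process over the full coverage window
  cov_weeks <- (as.integer(diagnosis_date) - as.integer(coverage_start_date)) / 7
  for (g in names(bg_codes)) {
    rate <- config$base_encounter_rates[[g]]
    if (rate <= 0) next
    counts <- rpois(n, rate * cov_weeks)
    if (!sum(counts)) next
    sc <- scatter(counts, coverage_start_date, diagnosis_date)
    k <- length(sc$idx)
    p <- blank(k)
    p$person_id <- person_id[sc$idx]
    p$date <- sc$date
    p$setting <- "physician_claim"
    p$diagnosis_code <- bg_codes[[g]]
    p$provider_specialty <- if (g == "primary_care") "family_physician" else "other"
    p$provider_id <- if (g == "primary_care") gp_id[sc$idx] else
      sprintf("SP%05d", sample.int(500L, k, replace = TRUE))
    p$origin <- "background"
    pieces[[length(pieces) + 1L]] <- p
  }

  # multiplied-rate cancer-signal process from onset to diagnosis
  signal_weeks <- (true_interval_days + 1L) / 7
  for (g in c("gi_endoscopy", "abdominal_imaging", "gi_physician")) {
    extra <- (config$signal_rate_multipliers[[g]] - 1) *
      config$base_encounter_rates[[g]]
    if (extra <= 0) next
    counts <- rpois(n, extra * signal_weeks)
    if (!sum(counts)) next
    sc <- scatter(counts, true_onset_date, diagnosis_date)
    k <- length(sc$idx)
    p <- blank(k)
    p$person_id <- person_id[sc$idx]
    p$date <- sc$date
    p$setting <- "physician_claim"
    p$provider_specialty <- "other"
    p$provider_id <- sprintf("SP%05d", sample.int(500L, k, replace = TRUE))
    p$origin <- "signal"
    if (g == "gi_physician") {
      # symptom-coded visits; never on or before the onset date for persons on
      # the no-symptom-recorded pathway
      sym <- runif(k) < config$signal_symptom_p
      sym <- sym & (!no_symptom[sc$idx] | sc$date > true_onset_date[sc$idx])
      p$diagnosis_code <- ifelse(sym, "GI_SYMPT", "GI_VISIT")
      p$is_symptom_code <- sym
    } else {
      p$diagnosis_code <- bg_codes[[g]]
    }
    pieces[[length(pieces) + 1L]] <- p
  }

  # presenting encounter on the true onset date
  sym_idx <- which(!no_symptom)
  if (length(sym_idx)) {
    k <- length(sym_idx)
    p <- blank(k)
    p$person_id <- person_id[sym_idx]
    p$date <- true_onset_date[sym_idx]
    p$setting <- "physician_claim"
    p$diagnosis_code <- "GI_SYMPT"
    p$provider_specialty <- "family_physician"
    p$provider_id <- gp_id[sym_idx]
    p$is_symptom_code <- TRUE
    p$origin <- "presenting"
    pieces[[length(pieces) + 1L]] <- p
  }
  ns_idx <- which(no_symptom)
  referred <- logical(n)
  if (length(ns_idx)) {
    k <- length(ns_idx)
    p <- blank(k)
    p$person_id <- person_id[ns_idx]
    p$date <- true_onset_date[ns_idx]
    p$setting <- "physician_claim"
    gfobt <- runif(k) < 0.7
    p$diagnosis_code <- ifelse(gfobt, "FOBT_G", "ENDO_COL")
    p$provider_specialty <- "other"
    p$provider_id <- sprintf("SP%05d", sample.int(500L, k, replace = TRUE))
    p$is_procedure <- TRUE
    p$procedure_kind <- ifelse(gfobt, "gFOBT", "lower_GI_scope")
    p$origin <- "presenting"
    ref <- runif(k) < config$referral_fraction
    p$referring_provider_id[ref] <- gp_id[ns_idx][ref]
    referred[ns_idx] <- ref
    pieces[[length(pieces) + 1L]] <- p
    # the referring physician visit the 365-day lookback should find
    ridx <- ns_idx[ref]
    if (length(ridx)) {
      kr <- length(ridx)
      r <- blank(kr)
      r$person_id <- person_id[ridx]
      r$date <- true_onset_date[ridx] - sample(7:60, kr, replace = TRUE)
      r$setting <- "physician_claim"
      r$diagnosis_code <- "PC_VISIT"
      r$provider_specialty <- "family_physician"
      r$provider_id <- gp_id[ridx]
      r$origin <- "referral"
      pieces[[length(pieces) + 1L]] <- r
    }
  }

  # workup procedures between onset and diagnosis (symptomatic persons)
  add_procs <- function(idx, code, kind) {
    if (!length(idx)) return()
    k <- length(idx)
    p <- blank(k)
    p$person_id <- person_id[idx]
    p$date <- runif_dates_between(true_onset_date[idx], diagnosis_date[idx])
    p$setting <- "physician_claim"
    p$diagnosis_code <- code
    p$provider_specialty <- "other"
    p$provider_id <- sprintf("SP%05d", sample.int(500L, k, replace = TRUE))
    p$is_procedure <- TRUE
    p$procedure_kind <- kind
    p$origin <- "workup"
    pieces[[length(pieces) + 1L]] <<- p
  }
  add_procs(which(has_col), "ENDO_COL", "lower_GI_scope")
  add_procs(which(has_img), sample(c("IMG_CT", "IMG_US"), sum(has_img),
                                   replace = TRUE), "imaging")

  # emergency visit on the diagnosis date (emergent diagnoses)
  em_idx <- which(emergent)
  if (length(em_idx)) {
    k <- length(em_idx)
    p <- blank(k)
    p$person_id <- person_id[em_idx]
    p$date <- diagnosis_date[em_idx]
    p$setting <- "emergency"
    p$diagnosis_code <- "GI_ED"
    p$provider_specialty <- "other"
    p$provider_id <- sprintf("ED%03d", sample.int(50L, k, replace = TRUE))
    p$is_symptom_code <- TRUE
    p$origin <- "emergent"
    pieces[[length(pieces) + 1L]] <- p
  }

  # mental-health encounters realizing the true exposure group
  pieces[[length(pieces) + 1L]] <-
    make_mh_encounters(person_id, spi_group, diagnosis_date, gp_id, dict)

  encounters <- dplyr::bind_rows(pieces)
  # drop anything generated before coverage starts (referral visits can fall
  # just outside for persons with injected short coverage)
  cov_lookup <- setNames(coverage_start_date, person_id)
  encounters <- encounters[encounters$date >= cov_lookup[encounters$person_id], ]
  encounters <- dplyr::arrange(encounters, person_id, date, diagnosis_code,
                               setting, origin)
  encounters$encounter_id <- sprintf("E%08d", seq_len(nrow(encounters)))
  encounters <- dplyr::relocate(encounters, encounter_id)

  list(
    persons = tibble::tibble(
      person_id, sex, birth_date, coverage_start_date, death_date,
      income_quintile, rio_score, comorbidity_score
    ),
    encounters = encounters,
    cancers = tibble::tibble(
      person_id, diagnosis_date, site_code, histology, stage,
      death_certificate_only, prior_malignancy
    ),
    truth = tibble::tibble(
      person_id, true_spi_group = spi_group, true_onset_date,
      true_interval_days, true_pathway,
      true_no_symptom = no_symptom, true_emergent = emergent,
      injected_short_coverage = short_coverage,
      injected_under_18 = under18,
      injected_invalid_death = invalid_death,
      referred
    )
  )
}

# uniform integer date in [from, to] elementwise
runif_dates_between <- function(from, to) {
  span <- as.integer(to) - as.integer(from)
  as.Date(as.integer(from) + floor(runif(length(from)) * (span + 1L)),
          origin = "1970-01-01")
}

# Mental-health encounter streams per exposure group. Exposure window is
# [diagnosis - 1825, diagnosis - 183] days; "none" persons occasionally get a
# visit strictly outside it so the window logic is exercised.
make_mh_encounters <- function(person_id, spi_group, diagnosis_date, gp_id,
                               dict) {
  n <- length(person_id)
  out <- list()
  emit <- function(idx, n_each, setting, specialty, codes, provider,
                   win_lo, win_hi) {
    i <- rep.int(idx, n_each)
    k <- length(i)
    if (!k) return()
    tibble::tibble(
      person_id = person_id[i],
      date = runif_dates_between(rep(win_lo[i], 1), rep(win_hi[i], 1)),
      setting = setting, diagnosis_code = sample(codes, k, replace = TRUE),
      provider_specialty = specialty,
      provider_id = if (identical(specialty, "family_physician")) gp_id[i] else
        sprintf("PSY%03d", sample.int(80L, k, replace = TRUE)),
      referring_provider_id = NA_character_,
      is_procedure = FALSE, procedure_kind = "none",
      is_symptom_code = FALSE, origin = "mental_health"
    ) -> p
    out[[length(out) + 1L]] <<- p
  }
  win_lo <- diagnosis_date - 1825L
  win_hi <- diagnosis_date - 183L

  ip <- which(spi_group == "inpatient")
  if (length(ip)) {
    emit(ip, 1L + rpois(length(ip), 0.5), "hospitalization", "psychiatrist",
         dict$spi_codes, NULL, win_lo, win_hi)
    extra <- rpois(length(ip), 0.8)
    emit(ip[extra > 0], extra[extra > 0], "physician_claim", "psychiatrist",
         dict$spi_codes, NULL, win_lo, win_hi)
  }
  op <- which(spi_group == "outpatient")
  if (length(op)) {
    n_vis <- 2L + rpois(length(op), 1)
    ed_split <- rbinom(length(op), n_vis, 0.4)
    emit(op[ed_split > 0], ed_split[ed_split > 0], "emergency", "other",
         dict$spi_codes, NULL, win_lo, win_hi)
    psy <- n_vis - ed_split
    emit(op[psy > 0], psy[psy > 0], "physician_claim", "psychiatrist",
         dict$spi_codes, NULL, win_lo, win_hi)
  }
  ic <- which(spi_group == "inconclusive")
  if (length(ic)) {
    variant <- sample.int(4L, length(ic), replace = TRUE)
    emit(ic[variant == 1], 1L, "physician_claim", "psychiatrist",
         dict$spi_codes, NULL, win_lo, win_hi)
    emit(ic[variant == 2], 1L, "emergency", "other",
         dict$spi_codes, NULL, win_lo, win_hi)
    v3 <- ic[variant == 3]
    emit(v3, 1L + rpois(length(v3), 1), "physician_claim", "family_physician",
         dict$spi_codes, NULL, win_lo, win_hi)
    v4 <- ic[variant == 4]
    nonspi <- setdiff(dict$mental_health_codes, dict$spi_codes)
    emit(v4, 1L + rpois(length(v4), 1), "physician_claim", "psychiatrist",
         nonspi, NULL, win_lo, win_hi)
  }
  # continuing mental-health care in the 6-month blackout for exposed and
  # inconclusive persons, at roughly the same daily rate as their in-window
  # care, so mental-health contact is a persistent process rather than a
  # spurious pre-diagnosis signal
  cont <- which(spi_group %in% c("inpatient", "outpatient", "inconclusive"))
  if (length(cont)) {
    k_cont <- rpois(length(cont), 0.3)
    emit(cont[k_cont > 0], k_cont[k_cont > 0], "physician_claim",
         "psychiatrist", dict$spi_codes, NULL,
         diagnosis_date - 182L, diagnosis_date)
  }
  no <- which(spi_group == "none")
  if (length(no)) {
    # occasional historical visit strictly before the window opens, so the
    # window's far boundary is exercised without creating in-window contact
    touched <- no[runif(length(no)) < 0.1]
    emit(touched, 1L, "physician_claim", "psychiatrist",
         dict$spi_codes, NULL, diagnosis_date - 2150L, diagnosis_date - 1826L)
  }
  dplyr::bind_rows(out)
}
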