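# Shared fixture builders and independent oracles.

DX <- as.Date("2015-06-15")

# Build an encounter table from minimal arguments; days_pre counts days
# before the diagnosis date DX (0 = on the diagnosis date).
enc <- function(days_pre, code = "GI_VISIT", setting = "physician_claim",
                specialty = "other", person = "P1", dx = DX,
                procedure = FALSE, kind = "none", symptom = FALSE,
                provider = NA_character_, referrer = NA_character_) {
  n <- length(days_pre)
  tibble::tibble(
    encounter_id = sprintf("F%03d", seq_len(n)),
    person_id = rep_len(person, n),
    date = dx - days_pre,
    setting = rep_len(setting, n),
    diagnosis_code = rep_len(code, n),
    provider_specialty = rep_len(specialty, n),
    provider_id = rep_len(provider, n),
    referring_provider_id = rep_len(referrer, n),
    is_procedure = rep_len(procedure, n),
    procedure_kind = rep_len(kind, n),
    is_symptom_code = rep_len(symptom, n)
  )
}

# Profile table for resolve_first_contact fixtures.
make_profiles <- function(groups, lookbacks, selected = TRUE) {
  tibble::tibble(
    group_label = groups,
    frequency_ratio = ifelse(rep_len(selected, length(groups)), 2, 1),
    selected = rep_len(selected, length(groups)),
    lookback_days = as.integer(lookbacks)
  )
}

# Independent re-statement of the SPI classification rules, written as
# literal nested conditions over one person's encounters (the truth table the
# vectorized classifier is checked against).
spi_oracle <- function(encounters, dx, dict = default_code_dictionary(),
                       distinct_dates = FALSE) {
  lab <- "none"
  n_out <- 0
  out_dates <- as.Date(character(0))
  saw_mh <- FALSE
  for (i in seq_len(nrow(encounters))) {
    row <- encounters[i, ]
    back <- as.integer(dx - row$date)
    if (back < 183 || back > 1825) next
    if (!(row$diagnosis_code %in% dict$mental_health_codes)) next
    saw_mh <- TRUE
    if (row$diagnosis_code %in% dict$spi_codes) {
      if (row$setting == "hospitalization") {
        return("inpatient")
      }
      is_ed <- row$setting == "emergency"
      is_psy <- row$setting == "physician_claim" &&
        row$provider_specialty == "psychiatrist"
      if (is_ed || is_psy) {
        n_out <- n_out + 1
        out_dates <- c(out_dates, row$date)
      }
    }
  }
  qualifying <- if (distinct_dates) length(unique(out_dates)) else n_out
  if (qualifying >= 2) return("outpatient")
  if (saw_mh) return("inconclusive")
  "none"
}

# Brute-force check-loss minimum: enumerate every p-subset of observations,
# fit the hyperplane through it exactly, and take the smallest objective.
# Exact for small n; independent of the simplex solver.
qr_bruteforce <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  best_beta <- NULL
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    beta <- solve(Xi, y[idx])
    obj <- check_loss(y - X %*% beta, tau)
    if (obj < best - 1e-12) {
      best <- obj
      best_beta <- beta
    }
  }
  list(objective = best, beta = best_beta)
}

# Brute-force first-contact resolution over one person's encounters: filter
# candidates group-by-group against each group's own window, pick the
# earliest (non-procedures first on ties), then apply the referral rule.
fc_oracle <- function(encounters, profiles, dx,
                      dict = default_code_dictionary()) {
  cand <- list()
  for (i in seq_len(nrow(encounters))) {
    row <- encounters[i, ]
    g <- unname(dict$encounter_groups[row$diagnosis_code])
    if (is.na(g)) next
    j <- which(profiles$group_label == g & profiles$selected)
    if (!length(j)) next
    back <- as.integer(dx - row$date)
    if (back < 0 || back > profiles$lookback_days[j]) next
    cand[[length(cand) + 1L]] <- row
  }
  if (!length(cand)) return(NULL)
  cand <- dplyr::bind_rows(cand)
  cand <- cand[order(cand$date, cand$is_procedure, cand$encounter_id), ]
  fc <- cand[1, ]
  start <- fc$date
  used_ref <- FALSE
  if (fc$is_procedure && !is.na(fc$referring_provider_id)) {
    prior <- encounters[
      !is.na(encounters$provider_id) &
        encounters$provider_id == fc$referring_provider_id &
        encounters$date < fc$date &
        encounters$date >= fc$date - 365L, ]
    if (nrow(prior)) {
      start <- max(prior$date)
      used_ref <- TRUE
    }
  }
  list(first_contact_date = fc$date, resolved_start_date = start,
       interval_days = as.integer(dx - start),
       used_referral_lookback = used_ref)
}

# Interval rows taken directly from ground truth (first contact = true
# onset); used to test classifiers in isolation from the interval engine.
truth_intervals <- function(truth, cancers) {
  d <- dplyr::inner_join(truth, cancers, by = "person_id")
  tibble::tibble(
    person_id = d$person_id,
    first_contact_date = d$true_onset_date,
    resolved_start_date = d$true_onset_date,
    interval_days = d$true_interval_days,
    used_referral_lookback = FALSE,
    identifiable = TRUE
  )
}

# Small, fast generator config used across tests.
quick_config <- function(n = 400, seed = 1, ...) {
  sim_config(n_persons = n, seed = seed, ...)
}
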