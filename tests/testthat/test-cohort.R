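persons_row <- function(person = "P1", birth = DX - round(55 * 365.25),
                        coverage = DX - 2000, death = as.Date(NA)) {
  tibble::tibble(
    person_id = person, sex = "female", birth_date = birth,
    coverage_start_date = coverage, death_date = death,
    income_quintile = 3L, rio_score = 10, comorbidity_score = 1L
  )
}

cancers_row <- function(person = "P1", dx = DX, site = "C18.2",
                        dco = FALSE, prior = FALSE) {
  tibble::tibble(
    person_id = person, diagnosis_date = dx, site_code = site,
    histology = "adenocarcinoma", stage = "II",
    death_certificate_only = dco, prior_malignancy = prior
  )
}

test_that("exclusion rules fire in order with one reason per person", {
  persons <- dplyr::bind_rows(
    persons_row("A", birth = DX - round(17 * 365.25)),        # age < 18
    persons_row("B", coverage = DX - 729),                     # < 2y coverage
    persons_row("C", coverage = DX - 730),                     # exactly 2y: kept
    persons_row("D", death = DX - 10),                         # invalid death
    persons_row("E"),                                          # DCO
    persons_row("F"),                                          # prior malignancy
    persons_row("G"),                                          # clean
    persons_row("H")                                           # wrong site
  )
  cancers <- dplyr::bind_rows(
    cancers_row("A"), cancers_row("B"), cancers_row("C"), cancers_row("D"),
    cancers_row("E", dco = TRUE), cancers_row("F", prior = TRUE),
    cancers_row("G"), cancers_row("H", site = "C18.1")
  )
  res <- apply_exclusions(persons, cancers)
  expect_setequal(res$included, c("C", "G"))
  ledger <- setNames(res$ledger$reason, res$ledger$person_id)
  expect_equal(ledger[["A"]], "age<18")
  expect_equal(ledger[["B"]], "coverage<2y")
  expect_equal(ledger[["D"]], "invalid_death_date")
  expect_equal(ledger[["E"]], "death_certificate_only")
  expect_equal(ledger[["F"]], "prior_malignancy")
  expect_equal(ledger[["H"]], "site_not_eligible")
  # accounting identity
  expect_equal(length(res$included) + nrow(res$ledger), nrow(persons))
  expect_equal(sum(res$counts), nrow(res$ledger))
  # duplicated index cancers are a data error
  expect_error(apply_exclusions(persons, dplyr::bind_rows(cancers, cancers_row("G"))),
               "Duplicate", class = "dxinterval_data_error")
})

test_that("injected short-coverage persons match the exclusion ledger count", {
  cfg <- quick_config(
    n = 2000, seed = 21,
    exclusion_fractions = c(short_coverage = 0.05, under_18 = 0,
                            invalid_death = 0, death_certificate_only = 0,
                            prior_malignancy = 0, other_site = 0)
  )
  tabs <- simulate_claims(cfg)
  res <- apply_exclusions(tabs$persons, tabs$cancers)
  expect_equal(unname(res$counts[["coverage<2y"]]),
               sum(tabs$truth$injected_short_coverage))
  expect_gt(res$counts[["coverage<2y"]], 0)
})

test_that("SPI classification reproduces the published examples", {
  # >= 1 eligible hospitalization in window -> inpatient
  r <- classify_spi(enc(300, code = "SCZ", setting = "hospitalization",
                        specialty = "psychiatrist"), DX)
  expect_equal(r$label, "inpatient")
  expect_length(r$qualifying_encounter_ids, 1)
  # two eligible psychiatrist claims, no hospitalization -> outpatient
  r <- classify_spi(enc(c(300, 400), code = "MDD",
                        specialty = "psychiatrist"), DX)
  expect_equal(r$label, "outpatient")
  # a single eligible psychiatrist claim -> inconclusive
  r <- classify_spi(enc(300, code = "MDD", specialty = "psychiatrist"), DX)
  expect_equal(r$label, "inconclusive")
  # eligible hospitalization inside the 6-month blackout only -> none
  r <- classify_spi(enc(100, code = "SCZ", setting = "hospitalization",
                        specialty = "psychiatrist"), DX)
  expect_equal(r$label, "none")
  # window endpoints are inclusive on both sides
  expect_equal(classify_spi(enc(183, code = "BIP", setting = "hospitalization"),
                            DX)$label, "inpatient")
  expect_equal(classify_spi(enc(1825, code = "BIP", setting = "hospitalization"),
                            DX)$label, "inpatient")
  expect_equal(classify_spi(enc(182, code = "BIP", setting = "hospitalization"),
                            DX)$label, "none")
  expect_equal(classify_spi(enc(1826, code = "BIP", setting = "hospitalization"),
                            DX)$label, "none")
  # family-physician-only SPI care is inconclusive, not outpatient
  r <- classify_spi(enc(c(300, 400), code = "MDD",
                        specialty = "family_physician"), DX)
  expect_equal(r$label, "inconclusive")
  # non-SPI mental-health code in any setting is inconclusive
  r <- classify_spi(enc(300, code = "ANX", setting = "hospitalization"), DX)
  expect_equal(r$label, "inconclusive")
  # two qualifying visits on the same day count as distinct rows by default
  same_day <- dplyr::bind_rows(
    enc(300, code = "MDD", setting = "emergency"),
    enc(300, code = "MDD", specialty = "psychiatrist")
  )
  expect_equal(classify_spi(same_day, DX)$label, "outpatient")
  expect_equal(classify_spi(same_day, DX, distinct_dates = TRUE)$label,
               "inconclusive")
})

test_that("classify_spi matches the hand-written truth table on every 1- and 2-encounter history", {
  archetypes <- expand.grid(
    days_pre = c(100, 900, 2000),
    setting = c("hospitalization", "emergency", "physician_claim"),
    specialty = c("psychiatrist", "family_physician", "other"),
    code = c("SCZ", "ANX", "GI_VISIT"),
    stringsAsFactors = FALSE
  )
  make <- function(i, id) {
    a <- archetypes[i, ]
    enc(a$days_pre, code = a$code, setting = a$setting,
        specialty = a$specialty)
  }
  n_arch <- nrow(archetypes)
  # all single-encounter histories
  for (i in seq_len(n_arch)) {
    h <- make(i)
    expect_equal(classify_spi(h, DX)$label, spi_oracle(h, DX),
                 info = paste("single archetype", i))
  }
  # all unordered pairs
  mismatch <- 0L
  for (i in seq_len(n_arch)) {
    for (j in i:n_arch) {
      h <- dplyr::bind_rows(make(i), make(j))
      if (!identical(classify_spi(h, DX)$label, spi_oracle(h, DX))) {
        mismatch <- mismatch + 1L
      }
    }
  }
  expect_equal(mismatch, 0L)
})

test_that("vectorized SPI classification agrees with the per-person classifier", {
  tabs <- simulate_claims(quick_config(n = 300, seed = 33))
  all_at_once <- dxinterval:::classify_spi_all(tabs$encounters, tabs$cancers)
  per_person <- vapply(seq_len(nrow(tabs$cancers)), function(i) {
    classify_spi(tabs$encounters, tabs$cancers$diagnosis_date[i],
                 person_id = tabs$cancers$person_id[i])$label
  }, character(1))
  expect_equal(all_at_once$spi, per_person)
})

test_that("adding an eligible hospitalization flips any outpatient case to inpatient", {
  tabs <- simulate_claims(quick_config(n = 400, seed = 44))
  labels <- dxinterval:::classify_spi_all(tabs$encounters, tabs$cancers)
  outpatients <- labels$person_id[labels$spi == "outpatient"]
  expect_gt(length(outpatients), 0)
  for (pid in head(outpatients, 5)) {
    dx <- tabs$cancers$diagnosis_date[tabs$cancers$person_id == pid]
    extra <- enc(400, code = "SCZ", setting = "hospitalization",
                 specialty = "psychiatrist", person = pid, dx = dx)
    augmented <- dplyr::bind_rows(tabs$encounters, extra)
    expect_equal(classify_spi(augmented, dx, person_id = pid)$label,
                 "inpatient")
  }
})

test_that("covariate derivation applies the published dichotomies and bands", {
  persons <- dplyr::bind_rows(
    persons_row("A"), persons_row("B"), persons_row("C"), persons_row("D")
  )
  persons$rio_score <- c(45, 44.9, 10, 80)
  persons$comorbidity_score <- c(3L, 4L, 0L, 7L)
  persons$birth_date <- c(DX - round(50 * 365.25) - 100,  # just past 50th bday
                          DX - round(50.99 * 365.25),     # 50 at last birthday
                          DX - round(51 * 365.25) - 10,   # 51
                          DX - round(81 * 365.25) - 10)   # > 80
  cancers <- dplyr::bind_rows(cancers_row("A"), cancers_row("B"),
                              cancers_row("C"), cancers_row("D"))
  cov <- derive_covariates(persons, cancers)
  expect_equal(cov$rural, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cov$more_comorbid, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cov$age_band, c("<=50", "<=50", "51-60", ">80"))
  expect_equal(cov$year, rep(2015L, 4))
})

test_that("build_cohort excludes inconclusive histories and keeps the ledger balanced", {
  tabs <- simulate_claims(quick_config(n = 800, seed = 55))
  built <- build_cohort(tabs$persons, tabs$encounters, tabs$cancers)
  expect_equal(nrow(built$cohort) + nrow(built$ledger), nrow(tabs$persons))
  expect_false(any(built$cohort$spi == "inconclusive"))
  expect_gt(sum(built$ledger$reason == "inconclusive_mh_history"), 0)
  # SPI labels broadly recover the injected groups (conclusive groups only)
  m <- dplyr::inner_join(built$cohort, tabs$truth, by = "person_id")
  agree <- mean(m$spi == m$true_spi_group)
  expect_gt(agree, 0.95)
})
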