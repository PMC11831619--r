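#' Default synthetic-code dictionary
#'
#' Encounter diagnosis/procedure codes in the generator are synthetic labels;
#' this dictionary maps them to encounter-type groups and flags the code sets
#' the classifiers need (eligible severe-psychiatric-illness codes, colonoscopy
#' codes, and so on). Real claims extracts can be analyzed by supplying a
#' dictionary that maps their native vocabularies onto the same slots.
#'
#' @return A list with elements:
#' \describe{
#'   \item{encounter_groups}{named character vector, code -> group label.}
#'   \item{spi_codes}{diagnosis codes eligible for the severe psychiatric
#'     illness (SPI) exposure definition.}
#'   \item{mental_health_codes}{all mental-health codes (SPI-eligible plus
#'     non-SPI); any in-window encounter with one of these that does not meet
#'     the SPI definition makes the history inconclusive.}
#'   \item{colonoscopy_codes}{procedure codes counted as colonoscopy in the
#'     diagnostic-pathway scan.}
#' }
#' @export
default_code_dictionary <- function() {
  list(
    encounter_groups = c(
      ENDO_COL = "gi_endoscopy", ENDO_SIG = "gi_endoscopy",
      ENDO_FUP = "gi_endoscopy", FOBT_G = "gi_endoscopy",
      IMG_CT = "abdominal_imaging", IMG_US = "abdominal_imaging",
      IMG_FUP = "abdominal_imaging",
      GI_SYMPT = "gi_physician", GI_VISIT = "gi_physician",
      GI_ED = "gi_physician",
      PC_VISIT = "primary_care", OTH_VISIT = "other_care",
      MDD = "mental_health", SCZ = "mental_health", BIP = "mental_health",
      PSY = "mental_health", ANX = "mental_health", ADJ = "mental_health"
    ),
    spi_codes = c("MDD", "SCZ", "BIP", "PSY"),
    mental_health_codes = c("MDD", "SCZ", "BIP", "PSY", "ANX", "ADJ"),
    colonoscopy_codes = "ENDO_COL"
  )
}

#' Build a simulation configuration
#'
#' Assembles (and validates) the full parameterization of the synthetic-claims
#' generator: cohort size, the exposure mixture, per-group background encounter
#' rates and post-onset rate multipliers, the true diagnostic-interval
#' distributions, pathway fractions, covariate distributions, and injected
#' exclusion fractions. Defaults encode the study conditions the package's
#' analyses are calibrated against; see the methods vignette for the rationale
#' behind each value.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed stored with the config (a `seed` argument to
#'   [simulate_claims()] overrides it).
#' @param ... Named overrides for any other configuration field.
#' @return A validated list of class `dx_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_persons = 200, seed = 42)
#' cfg$spi_mix
sim_config <- function(n_persons = 5000, seed = 1L, ...) {
  config <- list(
    schema_version = 1L,
    n_persons = n_persons,
    seed = as.integer(seed),
    # exposure mixture: mostly unexposed, as in population cancer registries
    spi_mix = c(none = 0.95, outpatient = 0.02, inpatient = 0.01,
                inconclusive = 0.02),
    # events per person-week; cancer-signal groups are rare at baseline
    base_encounter_rates = c(
      gi_endoscopy = 5e-4, abdominal_imaging = 5e-4, gi_physician = 5e-4,
      primary_care = 0.06, other_care = 0.04, mental_health = 0
    ),
    # applied to the base rate from true onset to diagnosis
    signal_rate_multipliers = c(
      gi_endoscopy = 25, abdominal_imaging = 20, gi_physician = 15,
      primary_care = 1, other_care = 1, mental_health = 1
    ),
    # true diagnostic-interval distributions, by SPI group, symptomatic persons
    true_interval_days = list(
      none         = list(family = "lognormal", median = 106, sigma = 0.6),
      outpatient   = list(family = "lognormal", median = 147, sigma = 0.6),
      inpatient    = list(family = "lognormal", median = 160, sigma = 0.6),
      inconclusive = list(family = "lognormal", median = 147, sigma = 0.6)
    ),
    # shorter intervals when detection starts from a screening-type test
    true_interval_no_symptom = list(
      none         = list(family = "lognormal", median = 69, sigma = 0.5),
      outpatient   = list(family = "lognormal", median = 67, sigma = 0.5),
      inpatient    = list(family = "lognormal", median = 62, sigma = 0.5),
      inconclusive = list(family = "lognormal", median = 67, sigma = 0.5)
    ),
    no_symptom_fraction = c(none = 0.191, outpatient = 0.134,
                            inpatient = 0.101, inconclusive = 0.16),
    emergent_fraction = 0.34,
    covariate_spec = list(
      none = list(sex_female_p = 0.447, age_mean = 71, age_sd = 13,
                  rural_p = 0.078, comorbid_ge4_p = 0.126,
                  income_quintile_p = c(0.197, 0.209, 0.201, 0.195, 0.198)),
      outpatient = list(sex_female_p = 0.537, age_mean = 66, age_sd = 13,
                        rural_p = 0.032, comorbid_ge4_p = 0.214,
                        income_quintile_p = c(0.280, 0.202, 0.182, 0.170, 0.166)),
      inpatient = list(sex_female_p = 0.524, age_mean = 66, age_sd = 13,
                       rural_p = 0.083, comorbid_ge4_p = 0.271,
                       income_quintile_p = c(0.337, 0.177, 0.172, 0.177, 0.137)),
      inconclusive = list(sex_female_p = 0.537, age_mean = 66, age_sd = 13,
                          rural_p = 0.032, comorbid_ge4_p = 0.214,
                          income_quintile_p = c(0.280, 0.202, 0.182, 0.170, 0.166))
    ),
    study_years = c(2007L, 2019L),
    coverage_days = 2200L,
    # fractions of persons injected to exercise each exclusion rule
    exclusion_fractions = c(
      short_coverage = 0.02, under_18 = 0.002, invalid_death = 0.002,
      death_certificate_only = 0.005, prior_malignancy = 0.03,
      other_site = 0.02
    ),
    referral_fraction = 0.3,
    procedure_probs = c(colonoscopy = 0.62, imaging = 0.58),
    signal_symptom_p = 0.6,
    dictionary = default_code_dictionary()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "dxinterval_config_error")
  }
  config[names(dots)] <- dots
  class(config) <- "dx_config"
  validate_config(config)
  config
}

#' Validate a simulation configuration
#'
#' Checks the generator invariants (mixture proportions sum to one, rates
#' non-negative, multipliers at least one, probabilities in \[0, 1\],
#' distribution specs well formed) and raises a configuration error naming the
#' offending field.
#'
#' @param config A `dx_config` list as built by [sim_config()].
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  required <- c("n_persons", "seed", "spi_mix", "base_encounter_rates",
                "signal_rate_multipliers", "true_interval_days",
                "true_interval_no_symptom", "no_symptom_fraction",
                "emergent_fraction", "covariate_spec", "study_years",
                "coverage_days", "exclusion_fractions", "referral_fraction",
                "procedure_probs", "signal_symptom_p", "dictionary")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(sprintf("Configuration is missing required field(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dxinterval_config_error")
  }
  spi_groups <- c("none", "outpatient", "inpatient", "inconclusive")

  check_config(length(config$n_persons) == 1 && config$n_persons >= 1 &&
                 config$n_persons == as.integer(config$n_persons),
               "n_persons", "must be a positive integer count")
  check_config(setequal(names(config$spi_mix), spi_groups) &&
                 all(config$spi_mix >= 0) &&
                 abs(sum(config$spi_mix) - 1) < 1e-9,
               "spi_mix",
               "must be proportions over none/outpatient/inpatient/inconclusive summing to 1")
  check_config(all(config$base_encounter_rates >= 0),
               "base_encounter_rates", "rates must be >= 0")
  check_config(setequal(names(config$signal_rate_multipliers),
                        names(config$base_encounter_rates)) &&
                 all(config$signal_rate_multipliers >= 1),
               "signal_rate_multipliers",
               "must cover every encounter group and be >= 1")
  grp <- config$dictionary$encounter_groups
  check_config(all(unique(grp) %in% names(config$base_encounter_rates)),
               "dictionary",
               "every encounter group in the dictionary needs a base rate")
  for (fld in c("true_interval_days", "true_interval_no_symptom")) {
    spec <- config[[fld]]
    check_config(setequal(names(spec), spi_groups), fld,
                 "needs one distribution per SPI group")
    for (g in spi_groups) {
      s <- spec[[g]]
      ok <- is.list(s) && s$family %in% c("lognormal", "fixed") &&
        (s$family != "lognormal" || (s$median > 0 && s$sigma >= 0)) &&
        (s$family != "fixed" || s$days >= 0)
      check_config(ok, fld,
                   sprintf("group '%s': family must be lognormal(median, sigma) or fixed(days)", g))
    }
  }
  check_config(setequal(names(config$no_symptom_fraction), spi_groups) &&
                 all(config$no_symptom_fraction >= 0 & config$no_symptom_fraction <= 1),
               "no_symptom_fraction", "must be per-group probabilities in [0, 1]")
  check_config(length(config$emergent_fraction) == 1 &&
                 config$emergent_fraction >= 0 && config$emergent_fraction <= 1,
               "emergent_fraction", "must be a probability in [0, 1]")
  check_config(setequal(names(config$covariate_spec), spi_groups),
               "covariate_spec", "needs one entry per SPI group")
  for (g in spi_groups) {
    cs <- config$covariate_spec[[g]]
    ok <- all(c("sex_female_p", "age_mean", "age_sd", "rural_p",
                "comorbid_ge4_p", "income_quintile_p") %in% names(cs)) &&
      all(unlist(cs[c("sex_female_p", "rural_p", "comorbid_ge4_p")]) >= 0) &&
      all(unlist(cs[c("sex_female_p", "rural_p", "comorbid_ge4_p")]) <= 1) &&
      length(cs$income_quintile_p) == 5 &&
      abs(sum(cs$income_quintile_p) - 1) < 1e-6
    check_config(ok, "covariate_spec",
                 sprintf("group '%s': probabilities in [0,1]; income quintile proportions must sum to 1", g))
  }
  check_config(all(config$exclusion_fractions >= 0 & config$exclusion_fractions <= 1),
               "exclusion_fractions", "must be probabilities in [0, 1]")
  check_config(config$referral_fraction >= 0 && config$referral_fraction <= 1,
               "referral_fraction", "must be a probability in [0, 1]")
  check_config(all(config$procedure_probs >= 0 & config$procedure_probs <= 1) &&
                 all(c("colonoscopy", "imaging") %in% names(config$procedure_probs)),
               "procedure_probs", "needs colonoscopy and imaging probabilities in [0, 1]")
  check_config(config$signal_symptom_p >= 0 && config$signal_symptom_p <= 1,
               "signal_symptom_p", "must be a probability in [0, 1]")
  check_config(length(config$study_years) == 2 &&
                 config$study_years[1] <= config$study_years[2],
               "study_years", "must be c(first_year, last_year)")
  check_config(config$coverage_days > 0, "coverage_days", "must be positive")
  invisible(config)
}

#' Read / write a simulation configuration as YAML
#'
#' The on-disk form is a single structured key-value file with a
#' `schema_version` field; [read_config()] validates after reading.
#'
#' @param path File path.
#' @param config A `dx_config` list.
#' @return `read_config()` returns a validated `dx_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L) {
    abort("Unsupported or missing config schema_version (expected 1)",
          class = "dxinterval_config_error")
  }
  # yaml round-trips named vectors as lists; restore the vector-valued fields
  vec_fields <- c("spi_mix", "base_encounter_rates", "signal_rate_multipliers",
                  "no_symptom_fraction", "exclusion_fractions",
                  "procedure_probs", "study_years")
  for (f in vec_fields) if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  raw$dictionary$encounter_groups <- unlist(raw$dictionary$encounter_groups)
  raw$dictionary$spi_codes <- unlist(raw$dictionary$spi_codes)
  raw$dictionary$mental_health_codes <- unlist(raw$dictionary$mental_health_codes)
  raw$dictionary$colonoscopy_codes <- unlist(raw$dictionary$colonoscopy_codes)
  for (g in names(raw$covariate_spec)) {
    raw$covariate_spec[[g]]$income_quintile_p <-
      unlist(raw$covariate_spec[[g]]$income_quintile_p)
  }
  class(raw) <- "dx_config"
  validate_config(raw)
  raw
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  prep <- unclass(config)
  # named vectors must be written as YAML maps or their names are lost
  named_vec_fields <- c("spi_mix", "base_encounter_rates",
                        "signal_rate_multipliers", "no_symptom_fraction",
                        "exclusion_fractions", "procedure_probs")
  for (f in named_vec_fields) prep[[f]] <- as.list(prep[[f]])
  prep$dictionary$encounter_groups <-
    as.list(prep$dictionary$encounter_groups)
  yaml::write_yaml(prep, path)
  invisible(path)
}
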