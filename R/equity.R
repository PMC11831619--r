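# Descriptive equity tables and the stratified quantile-regression analysis.

#' Chi-square test on a contingency table of counts
#'
#' Thin wrapper used for every categorical comparison in the descriptive
#' tables: Pearson chi-square without continuity correction (the tables
#' compared are large), returning the statistic and p-value.
#'
#' @param tab A matrix or table of counts.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Kruskal-Wallis test across groups
#'
#' Wrapper used for interval-distribution comparisons across exposure groups.
#'
#' @param y Numeric response.
#' @param g Group labels.
#' @return List with `statistic` and `p_value`.
#' @export
kruskal_p <- function(y, g) {
  res <- kruskal.test(y, factor(g))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Format a count and percentage
#'
#' @param num Numerator count(s).
#' @param denom Denominator count(s).
#' @param digits Decimal places for the percentage.
#' @return Character vector `"n (p%)"`.
#' @export
#' @examples
#' fmt_n_pct(43, 424) # "43 (10.1%)"
fmt_n_pct <- function(num, denom, digits = 1) {
  pct <- round(100 * num / denom, digits)
  sprintf("%d (%s%%)", num, formatC(pct, format = "f", digits = digits))
}

spi_levels <- c("none", "outpatient", "inpatient")

#' Descriptive cohort tables by exposure group
#'
#' Builds the two descriptive summaries of the analysis: demographic and
#' cancer characteristics by SPI group (counts and percentages per level,
#' chi-square p-value per variable) and the diagnostic-pathway summary
#' (symptom status counts, interval median/IQR/90th percentile per symptom
#' stratum with Kruskal-Wallis p-values, the eight-pathway breakdown among
#' symptomatic persons, and emergency presentation on the diagnosis date).
#' Percentiles use the lower-interpolation convention ([quantile_lower()]).
#' Empty groups are reported with zero counts and missing percentiles.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param intervals Interval table from [compute_intervals()].
#' @param pathways Pathway table from [classify_pathways()].
#' @return A list of tibbles: `table1` (demographics), `table1_tests`,
#'   `table2` (symptom status, pathway breakdown, emergency presentation),
#'   `table2_intervals` (numeric interval statistics per stratum and group),
#'   `table2_tests`.
#' @export
describe_cohort <- function(cohort, intervals, pathways) {
  d <- cohort |>
    dplyr::inner_join(dplyr::select(intervals, person_id, interval_days),
                      by = "person_id") |>
    dplyr::inner_join(pathways, by = "person_id")
  d$spi <- factor(d$spi, levels = spi_levels)

  cat_vars <- c("age_band", "sex", "rural", "more_comorbid",
                "income_quintile", "year", "histology", "stage")
  t1 <- list(); t1_tests <- list()
  group_n <- table(d$spi)
  for (v in cat_vars) {
    tab <- table(d[[v]], d$spi)
    rows <- tibble::tibble(
      variable = v,
      level = rownames(tab)
    )
    for (g in spi_levels) {
      rows[[g]] <- fmt_n_pct(tab[, g], group_n[[g]])
    }
    t1[[v]] <- rows
    pv <- if (all(dim(tab) >= c(2, 2)) && sum(tab) > 0) chisq_p(tab)$p_value
          else NA_real_
    t1_tests[[v]] <- tibble::tibble(variable = v, p_value = pv)
  }

  # pathway / interval summary
  strata <- c("no_symptom_recorded", "symptomatic")
  t2 <- list(); t2_iv <- list(); t2_tests <- list()
  for (s in strata) {
    ds <- d[d$symptom_status == s, ]
    row <- tibble::tibble(variable = "symptom_status", level = s)
    stat_rows <- tibble::tibble(
      stratum = s,
      statistic = c("median", "q1", "q3", "p90", "n")
    )
    for (g in spi_levels) {
      yg <- ds$interval_days[ds$spi == g]
      row[[g]] <- fmt_n_pct(length(yg), group_n[[g]])
      qs <- if (length(yg)) quantile_lower(yg, c(0.5, 0.25, 0.75, 0.9)) else
        rep(NA_real_, 4)
      stat_rows[[g]] <- c(qs, length(yg))
    }
    t2[[paste0("status_", s)]] <- row
    t2_iv[[s]] <- stat_rows
    t2_tests[[s]] <- tibble::tibble(
      variable = "interval", stratum = s,
      p_value = if (nrow(ds) && dplyr::n_distinct(ds$spi) > 1)
        kruskal_p(ds$interval_days, ds$spi)$p_value else NA_real_
    )
  }
  # chi-square across groups for the no-symptom vs symptomatic split
  split_tab <- table(d$symptom_status, d$spi)
  t2_tests$symptom_split <- tibble::tibble(
    variable = "symptom_status", stratum = NA_character_,
    p_value = if (all(dim(split_tab) >= c(2, 2))) chisq_p(split_tab)$p_value
              else NA_real_
  )
  # eight-pathway breakdown among symptomatic persons
  sym <- d[d$symptom_status == "symptomatic", ]
  sym_n <- table(sym$spi)
  pw_levels <- paste0(
    rep(c("colonoscopy_only", "colonoscopy_plus_imaging", "imaging_only",
          "neither"), each = 2),
    c("+ED", "+no_ED")
  )
  pw_tab <- table(factor(sym$pathway, levels = pw_levels), sym$spi)
  pw_rows <- tibble::tibble(variable = "pathway", level = pw_levels)
  for (g in spi_levels) {
    pw_rows[[g]] <- fmt_n_pct(pw_tab[, g], pmax(sym_n[[g]], 1L))
  }
  t2$pathways <- pw_rows
  ed_tab <- table(factor(sym$emergent, levels = c(FALSE, TRUE)), sym$spi)
  ed_row <- tibble::tibble(variable = "ed_on_diagnosis_date", level = "TRUE")
  for (g in spi_levels) {
    ed_row[[g]] <- fmt_n_pct(ed_tab["TRUE", g], pmax(sym_n[[g]], 1L))
  }
  t2$ed <- ed_row

  list(
    table1 = dplyr::bind_rows(t1),
    table1_tests = dplyr::bind_rows(t1_tests),
    table2 = dplyr::bind_rows(t2),
    table2_intervals = dplyr::bind_rows(t2_iv),
    table2_tests = dplyr::bind_rows(t2_tests)
  )
}

#' Stratified quantile-regression contrasts of the diagnostic interval
#'
#' The headline analysis: within each symptom stratum (a-priori
#' stratification) and for each quantile level (default 50th and 90th
#' percentiles), fits an unadjusted model (SPI group dummies, reference = no
#' SPI) and an adjusted model adding age (centered at the stratum median),
#' sex (female indicator, reference male), urban residence (reference rural)
#' and diagnosis year (centered at the last study year), so the adjusted
#' intercept is the interval for an unexposed rural male of median age
#' diagnosed in the final year. Comorbidity and income are deliberately never
#' adjusted for: both are taken to lie on the causal pathway between exposure
#' and interval (effect-decomposition confounder selection), so conditioning
#' on them would absorb part of the inequity being measured. Optionally adds
#' a sex-by-SPI interaction model.
#'
#' @param cohort,intervals,pathways Stage outputs (see [build_cohort()],
#'   [compute_intervals()], [classify_pathways()]).
#' @param taus Quantile levels.
#' @param boot Bootstrap replicates for confidence intervals.
#' @param seed Seed for bootstrap resampling.
#' @param min_stratum_n Strata smaller than this are skipped with a warning.
#' @param interaction If `TRUE`, also fits the sex-by-SPI interaction model.
#' @param center_year Year at which the year covariate is centered.
#' @return A tidy tibble: `stratum`, `tau`, `model`, `term`, `estimate`,
#'   `ci_lower`, `ci_upper`, `n_obs`.
#' @export
run_headline_analysis <- function(cohort, intervals, pathways,
                                  taus = c(0.5, 0.9), boot = 500L,
                                  seed = NULL, min_stratum_n = 50L,
                                  interaction = FALSE, center_year = NULL) {
  d <- cohort |>
    dplyr::inner_join(
      dplyr::select(intervals, person_id, interval_days), by = "person_id") |>
    dplyr::inner_join(
      dplyr::select(pathways, person_id, symptom_status), by = "person_id")
  d <- d[!is.na(d$interval_days), ]
  d$spi <- factor(d$spi, levels = spi_levels)
  if (is.null(center_year)) center_year <- max(d$year)

  results <- list()
  seeds <- if (is.null(seed)) rep(list(NULL), 64) else
    as.list(seed + seq_len(64))
  si <- 0L
  for (s in c("no_symptom_recorded", "symptomatic")) {
    ds <- d[d$symptom_status == s, ]
    if (nrow(ds) < min_stratum_n) {
      warn(sprintf("Stratum '%s' has %d observations (< %d): fits skipped",
                   s, nrow(ds), min_stratum_n))
      next
    }
    X_un <- spi_design(ds$spi)
    X_adj <- cbind(
      X_un,
      age = ds$age - median(ds$age),
      sex_female = as.numeric(ds$sex == "female"),
      urban = as.numeric(!ds$rural),
      year = ds$year - center_year
    )
    models <- list(unadjusted = X_un, adjusted = X_adj)
    if (interaction) {
      X_int <- cbind(
        X_adj,
        `inpatient:sex_female` = X_un[, "inpatient"] * (ds$sex == "female"),
        `outpatient:sex_female` = X_un[, "outpatient"] * (ds$sex == "female")
      )
      models$interaction <- X_int
    }
    for (tau in taus) {
      for (m in names(models)) {
        si <- si + 1L
        fit <- fit_quantile_regression(
          ds$interval_days, models[[m]], tau = tau, boot = boot,
          seed = seeds[[si]], stratum = s, adjusted = (m != "unadjusted")
        )
        results[[length(results) + 1L]] <- tibble::tibble(
          stratum = s, tau = tau, model = m,
          term = names(fit$coefficients),
          estimate = unname(fit$coefficients),
          ci_lower = unname(fit$ci_lower),
          ci_upper = unname(fit$ci_upper),
          n_obs = fit$n_obs
        )
      }
    }
  }
  dplyr::bind_rows(results)
}

# SPI dummy design (reference = none), dropping empty exposure levels.
spi_design <- function(spi) {
  X <- cbind(
    inpatient = as.numeric(spi == "inpatient"),
    outpatient = as.numeric(spi == "outpatient")
  )
  X[, colSums(X) > 0, drop = FALSE]
}

#' Interval distribution plot by pathway or stage
#'
#' Summary figure for symptomatic diagnoses: per exposure group and per
#' pathway (or stage), the median interval (point), the interquartile range
#' (line) and the 90th percentile (outer point).
#'
#' @param cohort,intervals,pathways Stage outputs.
#' @param by `"pathway"` or `"stage"`.
#' @return A ggplot object.
#' @export
plot_pathway_intervals <- function(cohort, intervals, pathways,
                                   by = c("pathway", "stage")) {
  by <- match.arg(by)
  d <- cohort |>
    dplyr::inner_join(dplyr::select(intervals, person_id, interval_days),
                      by = "person_id") |>
    dplyr::inner_join(dplyr::select(pathways, person_id, symptom_status,
                                    pathway), by = "person_id") |>
    dplyr::filter(symptom_status == "symptomatic")
  d$facet <- d[[by]]
  s <- d |>
    dplyr::group_by(facet, spi) |>
    dplyr::summarise(
      median = quantile_lower(interval_days, 0.5),
      q1 = quantile_lower(interval_days, 0.25),
      q3 = quantile_lower(interval_days, 0.75),
      p90 = quantile_lower(interval_days, 0.9),
      .groups = "drop"
    )
  ggplot2::ggplot(s, ggplot2::aes(y = spi, color = spi)) +
    ggplot2::geom_segment(ggplot2::aes(x = q1, xend = q3, yend = spi)) +
    ggplot2::geom_point(ggplot2::aes(x = median), size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = p90), shape = 1) +
    ggplot2::facet_wrap(~facet, ncol = 1) +
    ggplot2::labs(x = "Diagnostic interval (days)", y = NULL,
                  color = "SPI group") +
    ggplot2::theme_minimal()
}
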