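#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the synthetic study: cohort and panel sizes,
#' planted exposure effects (the ground truth later recovered by the
#' association and mediation stages), covariate effect sizes, noise levels,
#' and the PM10 process parameters. Defaults emulate a Po-valley panel of
#' overweight/obese adults: 1630 subjects, a 754-assay miRNA panel with four
#' internal controls, lognormal seasonal PM10 (annual mean 40 ug/m3,
#' winter-high), and covariate marginals matching the emulated study
#' population (73.1% female, mean age 52.4, 26.9% overweight vs obese,
#' median fibrinogen 325 mg/dl).
#'
#' Planted effects are expressed per 1 ug/m3 of PM10 on the transformed
#' outcome scale (natural log for EV counts and fibrinogen, log2 for miRNA
#' expression); use [beta_from_delta()] to convert a percent change per
#' 10 ug/m3 into a slope.
#'
#' @param n_subjects cohort size.
#' @param n_assays number of miRNA assays on the panel (controls excluded).
#' @param n_controls number of internal control assays (<= 4 named
#'   ath-miR159a, RNU48, RNU44, U6; ath-miR159a is an exogenous spike-in).
#' @param seed master RNG seed; every generator stream derives from it.
#' @param frac_never_amplified fraction of miRNA assays rendered unamplified
#'   in every subject.
#' @param effect_table named list of Day -1 PM10 slopes (per 1 ug/m3, ln
#'   scale) for EV outcomes `ev_nta`, `ev_cd61`, `ev_cd66`, `ev_epcam`,
#'   `ev_cd105`, `ev_cd14`. Each entry is either a scalar or a named vector
#'   `c(overweight = , obese = )` for a BMI-stratum-specific truth.
#' @param longterm_effect_table like `effect_table` but the slope multiplies
#'   the yearly-average PM10 channel.
#' @param assay_effects named numeric vector of planted log2-scale slopes on
#'   Day -1 PM10, names are assay ids (e.g. `"miR-0001"`).
#' @param mediation_spec list of `list(assay =, beta =, gamma =)`: per
#'   mediator the PM10 -> mediator path (log2 expression per ug/m3) and the
#'   mediator -> ln fibrinogen path.
#' @param gamma_pm10 direct PM10 -> ln fibrinogen slope (per ug/m3).
#' @param covariate_effects named list of slopes on every ln/log2 outcome for
#'   age (per year), female indicator, bmi (per kg/m2), smoking_former,
#'   smoking_current, app_temp (per deg C).
#' @param noise_sd named list: `ev` (ln EV counts), `fibrinogen`
#'   (ln fibrinogen), `crt` (well noise, cycles), `control_crt` (control
#'   assay noise, cycles).
#' @param pm10_mean annual-mean PM10, ug/m3 (geometric mean of the series).
#' @param pm10_sd log-scale day-to-day SD of PM10.
#' @param pm10_ar1 lag-1 autocorrelation of the log PM10 series, in (-1, 1).
#' @param pm10_seasonal_amplitude log-scale amplitude of the annual cycle
#'   (peak mid-January).
#' @param monitor_sd log-scale SD of monitor (site) levels.
#' @param year_sd log-scale SD of calendar-year levels (gives the yearly
#'   averages between-subject spread beyond siting).
#' @param frac_low_ampscore fraction of otherwise-amplified wells given an
#'   AmpScore below the QC threshold.
#' @param subject_rna_sd SD of the per-subject RNA-content offset (cycles)
#'   shared by all endogenous assays; normalization exists to remove it.
#' @param overweight_frac fraction of subjects in the overweight (25-30)
#'   BMI category; allocation is exact (rounded), the rest are obese.
#' @param fibrinogen_median baseline fibrinogen, mg/dl.
#' @param region_km edge of the square study region, km.
#' @return An object of class `evmir_config`.
#' @export
generator_config <- function(n_subjects = 1630L,
                             n_assays = 754L,
                             n_controls = 4L,
                             seed = 1L,
                             frac_never_amplified = 209 / 754,
                             effect_table = list(),
                             longterm_effect_table = list(),
                             assay_effects = numeric(),
                             mediation_spec = list(),
                             gamma_pm10 = 0,
                             covariate_effects = list(
                               age = 0.003, female = -0.05, bmi = 0.004,
                               smoking_former = 0.03, smoking_current = 0.08,
                               app_temp = -0.004
                             ),
                             noise_sd = list(ev = 0.5, fibrinogen = 0.17,
                                             crt = 0.8, control_crt = 0.15),
                             pm10_mean = 40,
                             pm10_sd = 0.45,
                             pm10_ar1 = 0.6,
                             pm10_seasonal_amplitude = 0.25,
                             monitor_sd = 0.12,
                             year_sd = 0.08,
                             frac_low_ampscore = 0.02,
                             subject_rna_sd = 0.2,
                             overweight_frac = 0.269,
                             fibrinogen_median = 325,
                             region_km = 100) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_assays = check_count(n_assays, "n_assays"),
    n_controls = check_count(n_controls, "n_controls", min = 0L),
    seed = check_count(seed, "seed", min = 0L),
    frac_never_amplified = check_scalar_number(frac_never_amplified,
      "frac_never_amplified", lower = 0, upper = 1, strict_upper = TRUE),
    effect_table = effect_table,
    longterm_effect_table = longterm_effect_table,
    assay_effects = assay_effects,
    mediation_spec = mediation_spec,
    gamma_pm10 = check_scalar_number(gamma_pm10, "gamma_pm10"),
    covariate_effects = covariate_effects,
    noise_sd = noise_sd,
    pm10_mean = check_scalar_number(pm10_mean, "pm10_mean", lower = 0,
                                    strict_lower = TRUE),
    pm10_sd = check_scalar_number(pm10_sd, "pm10_sd", lower = 0),
    pm10_ar1 = check_scalar_number(pm10_ar1, "pm10_ar1", lower = -1, upper = 1,
                                   strict_lower = TRUE, strict_upper = TRUE),
    pm10_seasonal_amplitude = check_scalar_number(pm10_seasonal_amplitude,
      "pm10_seasonal_amplitude", lower = 0),
    monitor_sd = check_scalar_number(monitor_sd, "monitor_sd", lower = 0),
    year_sd = check_scalar_number(year_sd, "year_sd", lower = 0),
    frac_low_ampscore = check_scalar_number(frac_low_ampscore,
      "frac_low_ampscore", lower = 0, upper = 1, strict_upper = TRUE),
    subject_rna_sd = check_scalar_number(subject_rna_sd, "subject_rna_sd",
                                         lower = 0),
    overweight_frac = check_scalar_number(overweight_frac, "overweight_frac",
      lower = 0, upper = 1),
    fibrinogen_median = check_scalar_number(fibrinogen_median,
      "fibrinogen_median", lower = 0, strict_lower = TRUE),
    region_km = check_scalar_number(region_km, "region_km", lower = 1)
  )
  for (nm in names(cfg$noise_sd)) {
    check_scalar_number(cfg$noise_sd[[nm]], paste0("noise_sd$", nm),
                        lower = 0, strict_lower = (nm != "control_crt"))
  }
  bad <- setdiff(names(cfg$effect_table), ev_outcome_names())
  if (length(bad))
    stop_invalid("effect_table names unknown outcome(s): %s",
                 paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$longterm_effect_table), ev_outcome_names())
  if (length(bad))
    stop_invalid("longterm_effect_table names unknown outcome(s): %s",
                 paste(bad, collapse = ", "))
  for (m in cfg$mediation_spec) {
    if (!all(c("assay", "beta", "gamma") %in% names(m)))
      stop_invalid("each mediation_spec entry needs fields assay, beta, gamma")
  }
  class(cfg) <- "evmir_config"
  cfg
}

ev_outcome_names <- function() {
  c("ev_nta", "ev_cd61", "ev_cd66", "ev_epcam", "ev_cd105", "ev_cd14")
}

# Generative covariate centers: slopes act on centered covariates so the
# planted intercepts stay interpretable as population medians.
covariate_centers <- function() {
  list(age = 52.4, female = 0.731, bmi = 33.6,
       smoking_former = 0.353, smoking_current = 0.158, app_temp = 12)
}

control_assay_names <- function(n_controls) {
  base <- c("ath-miR159a", "RNU48", "RNU44", "U6")
  if (n_controls <= 4L) return(base[seq_len(n_controls)])
  c(base, sprintf("CTL-%02d", seq_len(n_controls - 4L)))
}

#' Planted total PM10 effect on ln fibrinogen
#'
#' The decomposition identity of the generative model: the total planted
#' effect equals the planted direct path plus the sum of planted indirect
#' (product) paths, exactly by construction.
#'
#' @param config an `evmir_config`.
#' @return list with `direct`, `indirect` (per-mediator products), `total`.
#' @export
planted_total_effect <- function(config) {
  ind <- vapply(config$mediation_spec, function(m) m$beta * m$gamma, 0)
  names(ind) <- vapply(config$mediation_spec, function(m) as.character(m$assay), "")
  list(direct = config$gamma_pm10, indirect = ind,
       total = config$gamma_pm10 + sum(ind))
}

#' Generate a daily PM10 / meteorology exposure series
#'
#' Simulates monitor networks and daily series: log PM10 is the sum of a
#' fixed annual cosine cycle (winter-high), a calendar-year random level, a
#' monitor siting offset, and a stationary AR(1) day-to-day process; PM10 is
#' the exponential, hence lognormal. Temperature follows an annual cycle
#' (summer-high) with daily noise and relative humidity is drawn around 70%,
#' giving the inputs of [apparent_temperature()].
#'
#' @param config an `evmir_config`.
#' @param n_days number of calendar days (>= 8; >= 366 + enrollment span for
#'   long-term averages); series starts 2010-01-01.
#' @param n_monitors number of monitoring sites.
#' @return An object of class `exposure_series`: list with `monitors`
#'   (monitor_id, x, y) and `daily` (monitor_id, date, pm10, temperature, rh).
#' @export
generate_exposure <- function(config, n_days = 731L, n_monitors = 6L) {
  n_days <- check_count(n_days, "n_days", min = 8L)
  n_monitors <- check_count(n_monitors, "n_monitors", min = 1L)
  with_seed(string_seed(config$seed, "exposure"), {
    ids <- sprintf("M%02d", seq_len(n_monitors))
    mon <- data.frame(
      monitor_id = ids,
      x = stats::runif(n_monitors, 0, config$region_km),
      y = stats::runif(n_monitors, 0, config$region_km),
      stringsAsFactors = FALSE
    )
    site <- stats::rnorm(n_monitors, 0, config$monitor_sd)
    dates <- as.Date("2010-01-01") + seq_len(n_days) - 1L
    doy <- as.integer(format(dates, "%j"))
    years <- as.integer(format(dates, "%Y"))
    uyr <- sort(unique(years))
    yr_eff <- stats::rnorm(length(uyr), 0, config$year_sd)[match(years, uyr)]
    season_log <- config$pm10_seasonal_amplitude *
      cos(2 * pi * (doy - 15) / 365.25)
    innov_sd <- config$pm10_sd * sqrt(1 - config$pm10_ar1^2)
    daily <- vector("list", n_monitors)
    for (m in seq_len(n_monitors)) {
      e0 <- stats::rnorm(1, 0, config$pm10_sd)
      innov <- stats::rnorm(n_days, 0, innov_sd)
      ar <- as.numeric(stats::filter(innov, config$pm10_ar1,
                                     method = "recursive", init = e0))
      logpm <- log(config$pm10_mean) + season_log + yr_eff + site[m] + ar
      temp <- 13 + 11 * cos(2 * pi * (doy - 205) / 365.25) +
        stats::rnorm(n_days, 0, 3)
      rh <- pmin(pmax(stats::rnorm(n_days, 70, 12), 5), 100)
      daily[[m]] <- data.frame(
        monitor_id = ids[m], date = dates, pm10 = exp(logpm),
        temperature = temp, rh = rh, stringsAsFactors = FALSE
      )
    }
    structure(list(monitors = mon, daily = do.call(rbind, daily)),
              class = "exposure_series")
  })
}

#' Generate a synthetic cohort with planted exposure effects
#'
#' Draws covariates matching the emulated study's marginals (age truncated
#' normal 52.4 +/- 13.8 above 18, 73.1% female, smoking 48.7/35.3/15.8%
#' never/former/current, BMI >= 25 with exact overweight/obese allocation),
#' samples enrollment dates weighted to the autumn/winter-heavy recruitment
#' calendar, assigns each subject's lagged exposure via [assign_exposure()],
#' and generates the EV-count and fibrinogen outcomes from the planted
#' log-linear models:
#' `ln(EV_m) = alpha_m + beta_m * PM10(Day -1) + beta_m_yr * PM10(yearly) +
#' covariate terms + Normal(0, sd)`. Stratum-specific `beta_m` are supported
#' so interaction models have a planted truth. Covariates enter centered, so
#' intercepts are population medians. Fibrinogen here carries only the direct
#' PM10 path; [plant_mediation()] rebuilds it once mediating miRNAs exist.
#'
#' @param config an `evmir_config`.
#' @param exposure an `exposure_series` covering every subject's lag and
#'   long-term windows.
#' @param clinic_xy clinic coordinates (Day 0 exposure source); defaults to
#'   the region center.
#' @return data.frame (class `cohort_table`) with one row per subject:
#'   covariates, enrollment date and season, coordinates, assigned exposure
#'   columns (`pm10_lag0`..`pm10_lag7`, `pm10_6mo`, `pm10_1yr`,
#'   `app_temp_lag1`), EV outcomes and fibrinogen.
#' @export
generate_cohort <- function(config, exposure,
                            clinic_xy = rep(config$region_km / 2, 2)) {
  stopifnot(inherits(exposure, "exposure_series"))
  n <- config$n_subjects
  dates <- sort(unique(as.Date(exposure$daily$date)))
  eligible <- dates[dates - min(dates) >= 365]
  if (!length(eligible))
    stop_invalid("exposure series too short to cover a 1-year lookback")
  with_seed(string_seed(config$seed, "cohort"), {
    season_w <- c(winter = 0.299, spring = 0.264, summer = 0.131,
                  autumn = 0.307)
    w <- season_w[season_of(eligible)]
    enrollment <- sample(eligible, n, replace = TRUE, prob = w / sum(w))

    age <- truncated_normal(n, 52.4, 13.8, lower = 18)
    sex <- ifelse(stats::runif(n) < 0.731, "F", "M")
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.487, 0.353, 0.158))
    n_ow <- round(config$overweight_frac * n)
    bmi_category <- sample(rep(c("overweight", "obese"), c(n_ow, n - n_ow)))
    bmi <- ifelse(bmi_category == "overweight",
                  truncated_normal(n, 27.4, 1.5, lower = 25, upper = 30),
                  truncated_normal(n, 35.8, 4.5, lower = 30, upper = 60))

    cohort <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, bmi_category = bmi_category,
      smoking = smoking, enrollment_date = enrollment,
      season = season_of(enrollment),
      res_x = stats::runif(n, 0, config$region_km),
      res_y = stats::runif(n, 0, config$region_km),
      stringsAsFactors = FALSE
    )
    expo <- assign_exposure(cohort, exposure, clinic_xy)
    stopifnot(identical(expo$subject_id, cohort$subject_id))
    cohort <- cbind(cohort, expo[, -1L])

    lin <- covariate_linear_term(cohort, config$covariate_effects)
    pm1 <- cohort$pm10_lag1 - config$pm10_mean
    pmyr <- cohort$pm10_1yr - config$pm10_mean
    baselines <- c(ev_nta = log(2.5e10), ev_cd61 = log(2.0e8),
                   ev_cd66 = log(1.2e8), ev_epcam = log(4.0e7),
                   ev_cd105 = log(6.0e7), ev_cd14 = log(1.5e8))
    for (out in ev_outcome_names()) {
      b1 <- stratum_slope(config$effect_table[[out]], cohort$bmi_category)
      byr <- stratum_slope(config$longterm_effect_table[[out]],
                           cohort$bmi_category)
      lny <- baselines[[out]] + b1 * pm1 + byr * pmyr + lin +
        stats::rnorm(n, 0, config$noise_sd$ev)
      cohort[[out]] <- exp(lny)
    }
    lnf <- log(config$fibrinogen_median) + config$gamma_pm10 * pm1 + lin +
      stats::rnorm(n, 0, config$noise_sd$fibrinogen)
    cohort$fibrinogen <- exp(lnf)
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

stratum_slope <- function(entry, bmi_category) {
  if (is.null(entry)) return(0)
  if (length(entry) == 1L) return(rep(as.numeric(entry), length(bmi_category)))
  if (!all(c("overweight", "obese") %in% names(entry)))
    stop_invalid("stratum-specific effects need names 'overweight' and 'obese'")
  as.numeric(entry[bmi_category])
}

covariate_linear_term <- function(cohort, eff) {
  cen <- covariate_centers()
  eff$age * (cohort$age - cen$age) +
    eff$female * ((cohort$sex == "F") - cen$female) +
    eff$bmi * (cohort$bmi - cen$bmi) +
    eff$smoking_former * ((cohort$smoking == "former") - cen$smoking_former) +
    eff$smoking_current * ((cohort$smoking == "current") - cen$smoking_current) +
    eff$app_temp * (cohort$app_temp_lag1 - cen$app_temp)
}

#' Generate a Crt/AmpScore panel with planted PM10 slopes
#'
#' True log2 expression of assay j in subject i is
#' `x_ij = a_j + s_i + b_j * (PM10(Day -1) - mean) + e_ij` with baseline
#' `a_j`, shared subject RNA-content offset `s_i`, planted slope `b_j`
#' (zero unless named in `assay_effects` or `mediation_spec`), and well
#' noise. Crt is `28 - x_ij`, clipped below at 10, mapping the Crt > 28 QC
#' threshold onto "undetectable" naturally. Exactly
#' `round(frac_never_amplified * n_assays)` non-planted assays are rendered
#' unamplified (missing Crt) in every subject, and a random sprinkle of
#' wells receives an AmpScore below 1.1. Endogenous control assays are
#' expression-stable (no PM10 slope, reduced noise); the exogenous spike-in
#' control also lacks the subject offset.
#'
#' @param config an `evmir_config`.
#' @param cohort cohort from [generate_cohort()] (needs `pm10_lag1`).
#' @param exposure unused placeholder kept so generation stages share one
#'   signature; the panel reads exposure through `cohort`.
#' @return An object of class `crt_panel`: list with matrices `crt` and
#'   `ampscore` (subjects x assays, shared dimnames), `assay_ids`,
#'   `control_ids`, `subject_ids`, and `never_amplified` (the planted ids).
#' @export
generate_crt_panel <- function(config, cohort, exposure = NULL) {
  n <- nrow(cohort)
  na_ct <- config$n_assays
  mir_ids <- sprintf("miR-%04d", seq_len(na_ct))
  ctl_ids <- control_assay_names(config$n_controls)
  planted <- unique(c(names(config$assay_effects),
                      vapply(config$mediation_spec,
                             function(m) as.character(m$assay), "")))
  planted <- planted[planted != ""]
  if (!all(planted %in% mir_ids))
    stop_invalid("planted assay id(s) not on the panel: %s",
                 paste(setdiff(planted, mir_ids), collapse = ", "))
  if (na_ct < config$n_controls + length(config$mediation_spec))
    stop_invalid("n_assays must be >= n_controls + number of mediators")

  k_exact <- config$frac_never_amplified * na_ct
  k <- round(k_exact)
  if (abs(k_exact - k) > 1e-9)
    warning(sprintf(
      "frac_never_amplified * n_assays = %.3f is not a whole count; rounding to %d",
      k_exact, k), call. = FALSE)

  with_seed(string_seed(config$seed, "crt"), {
    slopes <- stats::setNames(numeric(na_ct), mir_ids)
    slopes[names(config$assay_effects)] <- as.numeric(config$assay_effects)
    for (m in config$mediation_spec) slopes[[as.character(m$assay)]] <- m$beta

    a <- stats::runif(na_ct, -1, 8)
    a[mir_ids %in% planted] <- 6 # planted assays are well-expressed
    s_i <- stats::rnorm(n, 0, config$subject_rna_sd)
    pm1 <- cohort$pm10_lag1 - config$pm10_mean

    x <- outer(s_i, a, "+") + outer(pm1, slopes) +
      matrix(stats::rnorm(n * na_ct, 0, config$noise_sd$crt), n, na_ct)
    crt <- pmax(28 - x, 10)

    never <- sample(setdiff(mir_ids, planted), k)
    crt[, match(never, mir_ids)] <- NA_real_

    amp <- matrix(stats::runif(n * na_ct, 1.2, 2), n, na_ct)
    low <- matrix(stats::runif(n * na_ct) < config$frac_low_ampscore, n, na_ct)
    amp[low] <- stats::runif(sum(low), 0.2, 1.05)
    amp[, match(never, mir_ids)] <- stats::runif(n * k, 0, 1.0)

    if (config$n_controls > 0L) {
      ctl_x <- matrix(8, n, config$n_controls) +
        matrix(stats::rnorm(n * config$n_controls, 0,
                            config$noise_sd$control_crt),
               n, config$n_controls)
      endo <- ctl_ids != "ath-miR159a"
      ctl_x[, endo] <- ctl_x[, endo] + s_i
      crt <- cbind(crt, pmax(28 - ctl_x, 10))
      amp <- cbind(amp, matrix(stats::runif(n * config$n_controls, 1.5, 2),
                               n, config$n_controls))
    }
    ids <- c(mir_ids, ctl_ids)
    dimnames(crt) <- dimnames(amp) <- list(cohort$subject_id, ids)
    structure(list(crt = crt, ampscore = amp, assay_ids = ids,
                   control_ids = ctl_ids, subject_ids = cohort$subject_id,
                   never_amplified = never,
                   planted_slopes = slopes[slopes != 0]),
              class = "crt_panel")
  })
}

#' Plant the mediated fibrinogen outcome
#'
#' Rebuilds ln(fibrinogen) as
#' `gamma_0 + gamma_PM10 * PM10(Day -1) + sum(gamma_M * M) + covariates +
#' noise`, where each mediator M is the control-pair normalized log2
#' expression of the specified panel assay, computed exactly as the analysis
#' stage computes it (QC, never-amplified removal, endogenous + exogenous
#' control normalization). Mediators enter centered at their cohort mean so
#' the intercept stays the population median. The planted total PM10 effect
#' is `gamma_PM10 + sum(beta * gamma)` ([planted_total_effect()]).
#'
#' @param config an `evmir_config` with a non-empty `mediation_spec` (an
#'   empty spec reduces to the direct-only fibrinogen model).
#' @param cohort cohort from [generate_cohort()].
#' @param panel panel from [generate_crt_panel()].
#' @return The cohort with `fibrinogen` replaced.
#' @export
plant_mediation <- function(config, cohort, panel) {
  stopifnot(inherits(panel, "crt_panel"))
  med_ids <- vapply(config$mediation_spec, function(m) as.character(m$assay), "")
  bad <- intersect(med_ids, panel$never_amplified)
  if (length(bad))
    stop_invalid("mediation_spec assay(s) flagged never-amplified: %s",
                 paste(bad, collapse = ", "))
  n <- nrow(cohort)
  contrib <- 0
  if (length(med_ids)) {
    qc <- apply_qc(panel, qc_config())
    kept <- drop_never_amplified(qc)$panel
    expr <- normalize_expression(kept, normalizer_control_pair())
    for (m in config$mediation_spec) {
      M <- expr$log2_values[, as.character(m$assay)]
      contrib <- contrib + m$gamma * (M - mean(M))
    }
  }
  lin <- covariate_linear_term(cohort, config$covariate_effects)
  pm1 <- cohort$pm10_lag1 - config$pm10_mean
  lnf <- with_seed(string_seed(config$seed, "fibrinogen"),
    log(config$fibrinogen_median) + config$gamma_pm10 * pm1 + contrib + lin +
      stats::rnorm(n, 0, config$noise_sd$fibrinogen))
  cohort$fibrinogen <- exp(lnf)
  cohort
}

#' Generate and write a full synthetic study
#'
#' Runs the whole generative chain (exposure series, cohort, Crt panel,
#' mediated fibrinogen) and, if `out_dir` is given, writes `cohort.csv`,
#' `exposure.csv`, `crt.csv`, `ampscore.csv` and `truth.json` (every planted
#' parameter) as plain UTF-8 CSV/JSON.
#'
#' @param config an `evmir_config`.
#' @param out_dir optional output directory (created if missing).
#' @param n_days,n_monitors passed to [generate_exposure()].
#' @return list with `exposure`, `cohort`, `panel`, `truth` (invisibly when
#'   writing).
#' @export
simulate_study <- function(config, out_dir = NULL, n_days = 731L,
                           n_monitors = 6L) {
  exposure <- generate_exposure(config, n_days, n_monitors)
  cohort <- generate_cohort(config, exposure)
  panel <- generate_crt_panel(config, cohort)
  cohort <- plant_mediation(config, cohort, panel)
  truth <- list(
    seed = config$seed,
    effect_table = config$effect_table,
    longterm_effect_table = config$longterm_effect_table,
    assay_effects = as.list(config$assay_effects),
    mediation = planted_total_effect(config),
    never_amplified = panel$never_amplified
  )
  res <- list(exposure = exposure, cohort = cohort, panel = panel,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mon <- exposure$monitors
    daily <- merge(exposure$daily, mon, by = "monitor_id", sort = FALSE)
    utils::write.csv(daily, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cohort), file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    write_matrix_csv(panel$crt, file.path(out_dir, "crt.csv"))
    write_matrix_csv(panel$ampscore, file.path(out_dir, "ampscore.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read back an exposure series written by [simulate_study()]
#'
#' @param path path to `exposure.csv`.
#' @return An `exposure_series` object.
#' @export
read_exposure_csv <- function(path) {
  daily <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily$date <- as.Date(daily$date)
  mon <- unique(daily[, c("monitor_id", "x", "y")])
  rownames(mon) <- NULL
  structure(list(monitors = mon,
                 daily = daily[, c("monitor_id", "date", "pm10",
                                   "temperature", "rh")]),
            class = "exposure_series")
}

#' Read back a Crt/AmpScore panel written by [simulate_study()]
#'
#' @param crt_path,ampscore_path CSV paths (subjects x assays, first column
#'   `subject_id`).
#' @param control_ids assay ids to treat as internal controls.
#' @return A `crt_panel` object.
#' @export
read_crt_panel <- function(crt_path, ampscore_path,
                           control_ids = c("ath-miR159a", "RNU48", "RNU44",
                                           "U6")) {
  as_mat <- function(p) {
    df <- utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$subject_id
    storage.mode(m) <- "double"
    m
  }
  crt <- as_mat(crt_path)
  amp <- as_mat(ampscore_path)
  stopifnot(identical(dim(crt), dim(amp)),
            identical(dimnames(crt), dimnames(amp)))
  structure(list(crt = crt, ampscore = amp, assay_ids = colnames(crt),
                 control_ids = intersect(control_ids, colnames(crt)),
                 subject_ids = rownames(crt),
                 never_amplified = character()),
            class = "crt_panel")
}
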