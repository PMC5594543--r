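test_that("config validation rejects out-of-range parameters and unknown outcomes", {
  expect_error(generator_config(frac_never_amplified = 1), "frac_never_amplified")
  expect_error(generator_config(pm10_ar1 = 1), "pm10_ar1")
  expect_error(generator_config(noise_sd = list(ev = 0, fibrinogen = 0.1,
                                                crt = 0.5, control_crt = 0.1)),
               "noise_sd")
  expect_error(generator_config(effect_table = list(not_an_outcome = 0.1)),
               "unknown outcome")
})

test_that("exposure generation is deterministic and degenerates to a constant series", {
  cfg <- generator_config(n_subjects = 10, seed = 1)
  e1 <- generate_exposure(cfg, n_days = 100, n_monitors = 3)
  e2 <- generate_exposure(cfg, n_days = 100, n_monitors = 3)
  expect_identical(e1, e2)

  cfg0 <- generator_config(n_subjects = 10, seed = 1, pm10_sd = 0,
                           pm10_ar1 = 0, pm10_seasonal_amplitude = 0,
                           monitor_sd = 0, year_sd = 0)
  e0 <- generate_exposure(cfg0, n_days = 50, n_monitors = 2)
  expect_equal(e0$daily$pm10, rep(40, 100), tolerance = 1e-12)
  expect_error(generate_exposure(cfg, n_days = 5), "n_days")
})

test_that("log PM10 series has the configured lag-1 autocorrelation", {
  cfg <- generator_config(n_subjects = 10, seed = 5, pm10_ar1 = 0.6,
                          pm10_seasonal_amplitude = 0, year_sd = 0,
                          monitor_sd = 0)
  e <- generate_exposure(cfg, n_days = 10000, n_monitors = 1)
  x <- log(e$daily$pm10)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.6), 0.05)
})

test_that("cohort marginals resemble the emulated population at the default size", {
  cfg <- generator_config(seed = 4)
  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 5)
  co <- generate_cohort(cfg, ex)
  expect_equal(nrow(co), 1630L)
  expect_gt(mean(co$sex == "F"), 0.69); expect_lt(mean(co$sex == "F"), 0.77)
  expect_lt(abs(mean(co$age) - 52.4), 1.5)
  expect_true(all(co$bmi >= 25))
  expect_identical(sum(co$bmi_category == "overweight"), 438L)
  expect_true(all((co$bmi < 30) == (co$bmi_category == "overweight")))
  med <- median(co$fibrinogen)
  expect_gt(med, 290); expect_lt(med, 366)
  expect_true(all(co$fibrinogen > 0))
  expect_true(all(as.matrix(co[, c("ev_nta", "ev_cd61", "ev_cd14")]) > 0))
  # season is consistent with the enrollment date
  expect_identical(co$season,
                   evmir:::season_of(co$enrollment_date))
})

test_that("null effects give associations centered at zero", {
  deltas <- vapply(1:5, function(r) {
    cfg <- generator_config(n_subjects = 400, seed = 100 + r)
    ex <- generate_exposure(cfg, n_days = 731, n_monitors = 3)
    co <- generate_cohort(cfg, ex)
    fit_adjusted(co, model_spec("ev_nta", "ln"))$delta_pct
  }, 0)
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(5) + 0.5)
})

test_that("crt panel plants the exact never-amplified count and is reproducible", {
  cfg <- generator_config(n_subjects = 40, n_assays = 754,
                          frac_never_amplified = 209 / 754, seed = 2)
  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 2)
  co <- generate_cohort(cfg, ex)
  p1 <- generate_crt_panel(cfg, co)
  p2 <- generate_crt_panel(cfg, co)
  expect_identical(p1, p2)
  expect_length(p1$never_amplified, 209L)
  expect_true(all(is.na(p1$crt[, p1$never_amplified])))
  expect_equal(ncol(p1$crt), 758L) # 754 miRNAs + 4 controls
  expect_true(all(p1$ampscore >= 0 & p1$ampscore <= 2))
  expect_true(all(p1$crt >= 10, na.rm = TRUE))

  cfg_frac <- generator_config(n_subjects = 10, n_assays = 5,
                               frac_never_amplified = 0.5, seed = 2)
  ex2 <- generate_exposure(cfg_frac, n_days = 731, n_monitors = 2)
  co2 <- generate_cohort(cfg_frac, ex2)
  expect_warning(generate_crt_panel(cfg_frac, co2), "rounding")
})

test_that("whole-study simulation writes byte-identical CSV outputs for the same seed", {
  cfg <- generator_config(n_subjects = 25, n_assays = 20, seed = 7,
                          frac_never_amplified = 0.2)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_study(cfg, d1, n_days = 731, n_monitors = 2)
  simulate_study(cfg, d2, n_days = 731, n_monitors = 2)
  for (f in c("cohort.csv", "exposure.csv", "crt.csv", "ampscore.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # round-trip readers reproduce the in-memory objects
  sim <- simulate_study(cfg, n_days = 731, n_monitors = 2)
  ex2 <- read_exposure_csv(file.path(d1, "exposure.csv"))
  expect_equal(ex2$daily$pm10, sim$exposure$daily$pm10, tolerance = 1e-6)
  pan2 <- read_crt_panel(file.path(d1, "crt.csv"),
                         file.path(d1, "ampscore.csv"))
  expect_equal(unname(pan2$crt), unname(sim$panel$crt), tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mediation planting obeys the exact decomposition and rejects dead mediators", {
  spec <- list(
    list(assay = "miR-0001", beta = -0.02, gamma = -0.03),
    list(assay = "miR-0002", beta = -0.015, gamma = 0.02)
  )
  cfg <- generator_config(n_subjects = 60, n_assays = 20, seed = 11,
                          frac_never_amplified = 0, mediation_spec = spec,
                          gamma_pm10 = 0.001)
  tot <- planted_total_effect(cfg)
  expect_equal(tot$total, 0.001 + (-0.02 * -0.03) + (-0.015 * 0.02),
               tolerance = 1e-15)
  expect_equal(tot$total, tot$direct + sum(tot$indirect), tolerance = 1e-15)

  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 2)
  co <- generate_cohort(cfg, ex)
  pan <- generate_crt_panel(cfg, co)
  co2 <- plant_mediation(cfg, co, pan)
  expect_false(identical(co2$fibrinogen, co$fibrinogen))
  expect_true(all(co2$fibrinogen > 0))

  pan_bad <- pan
  pan_bad$never_amplified <- c(pan$never_amplified, "miR-0001")
  expect_error(plant_mediation(cfg, co, pan_bad), "never-amplified")
})

test_that("planted mediation with a null direct path yields an indirect-only decomposition", {
  spec <- list(list(assay = "miR-0001",
                    beta = beta_from_delta(-15, "log2"), gamma = -0.05))
  cfg <- generator_config(n_subjects = 800, n_assays = 10, seed = 17,
                          frac_never_amplified = 0, mediation_spec = spec,
                          gamma_pm10 = 0)
  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 3)
  co <- generate_cohort(cfg, ex)
  pan <- generate_crt_panel(cfg, co)
  co <- plant_mediation(cfg, co, pan)
  qc <- drop_never_amplified(apply_qc(pan))$panel
  expr <- normalize_expression(qc, normalizer_control_pair())
  co$M <- expr$log2_values[, "miR-0001"]
  mspec <- mediation_model_spec(mediator = "M", n_boot = 2000, seed = 3)
  pt <- fit_mediation(co, mspec)
  bt <- suppressWarnings(bc_bootstrap_ci(co, mspec))
  # direct path is null by construction; indirect carries the whole effect
  dse <- summary(lm(log(fibrinogen) ~ pm10_lag1 + M + age + sex + bmi +
                      smoking + app_temp_lag1, co))$coefficients
  expect_lt(abs(pt$direct), 2 * dse["pm10_lag1", 2])
  expect_true(bt$ci[1] > 0) # indirect CI excludes zero (planted product > 0)
  expect_equal(pt$indirect, spec[[1]]$beta * spec[[1]]$gamma,
               tolerance = 8 * abs(spec[[1]]$beta * spec[[1]]$gamma))
})
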