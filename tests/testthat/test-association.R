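test_that("fit_adjusted matches an independent normal-equations oracle on a 12-row dataset", {
  set.seed(10)
  n <- 12
  df <- data.frame(
    pm10_lag1 = runif(n, 20, 80),
    age = rnorm(n, 50, 10),
    bmi = runif(n, 25, 40)
  )
  df$y <- exp(0.004 * df$pm10_lag1 + 0.01 * df$age + rnorm(n, 0, 0.1))
  spec <- model_spec("y", "ln", covariates = c("age", "bmi"))
  fit <- fit_adjusted(df, spec)

  X <- cbind(1, df$pm10_lag1, df$age, df$bmi)
  b <- solve(t(X) %*% X, t(X) %*% log(df$y))
  res <- log(df$y) - X %*% b
  s2 <- sum(res^2) / (n - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$beta, b[2, 1], tolerance = 1e-10)
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$p_raw, 2 * pt(abs(b[2, 1] / se), n - 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(fit$delta_pct, (exp(10 * fit$beta) - 1) * 100, tolerance = 1e-12)
  expect_true(fit$ci_low_pct <= fit$delta_pct && fit$delta_pct <= fit$ci_high_pct)
})

test_that("fit_adjusted recovers a planted slope in the noiseless limit and ignores row order", {
  df <- make_analysis_df(200, seed = 2, beta = log(1.0527) / 10, sigma = 1e-9)
  spec <- model_spec("y", "ln", covariates = c("age", "sex"))
  fit <- fit_adjusted(df, spec)
  expect_equal(fit$beta, log(1.0527) / 10, tolerance = 1e-6)

  df2 <- df[sample(nrow(df)), ]
  fit2 <- fit_adjusted(df2, spec)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
  expect_equal(fit2$p_raw, fit$p_raw, tolerance = 1e-12)
})

test_that("fit_adjusted reports collinear designs and drops incomplete rows", {
  df <- make_analysis_df(50, seed = 3)
  df$age2 <- df$age # exact collinearity
  expect_error(fit_adjusted(df, model_spec("y", "ln",
                                           covariates = c("age", "age2"))),
               "singular|collinear")
  df$age[1:4] <- NA
  fit <- fit_adjusted(df, model_spec("y", "ln", covariates = c("age", "sex")))
  expect_equal(fit$n_used, 46L)
  expect_equal(fit$n_dropped, 4L)
})

test_that("delta_pct follows both footnote formulas and round-trips to 1e-10", {
  expect_equal(delta_pct(0, "ln"), 0)
  expect_equal(delta_pct(0, "log2"), 0)
  expect_equal(delta_pct(log(1.035) / 10, "ln"), 3.5, tolerance = 1e-10)
  expect_equal(delta_pct(-0.00620, "log2"), (2^(-0.062) - 1) * 100,
               tolerance = 1e-12)
  # magnitude/sign cross-check against the validated-assay convention
  expect_equal(round(delta_pct(-0.0061934, "log2"), 2), -4.20)

  for (tr in c("ln", "log2")) {
    betas <- seq(-0.06, 0.02, length.out = 23)
    expect_equal(beta_from_delta(delta_pct(betas, tr), tr), betas,
                 tolerance = 1e-10)
  }
})

test_that("bh_fdr reproduces the hand step-up example and its invariants", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(6)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  # FDR<0.1 set never grows when p-values increase elementwise
  worse <- pmin(p * 1.5, 1)
  expect_true(all(which(bh_fdr(worse) < 0.1) %in% which(adj < 0.1)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_screen_fixture <- function(n = 120, n_assays = 15, seed = 8,
                                planted = numeric()) {
  cfg <- generator_config(n_subjects = n, n_assays = n_assays, seed = seed,
                          frac_never_amplified = 0,
                          assay_effects = planted)
  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 3)
  co <- generate_cohort(cfg, ex)
  pan <- generate_crt_panel(cfg, co)
  kept <- drop_never_amplified(apply_qc(pan))$panel
  list(expr = normalize_expression(kept, normalizer_global_mean()),
       cohort = co)
}

test_that("run_screening agrees with per-assay fit_adjusted and isolates degenerate assays", {
  fx <- make_screen_fixture()
  scr <- run_screening(fx$expr, fx$cohort)
  for (aid in scr$assay[c(1, 5, 9)]) {
    dat <- fx$cohort
    dat$expr_lin <- fx$expr$values[, aid]
    f <- fit_adjusted(dat, model_spec("expr_lin", "log2"))
    row <- scr[scr$assay == aid, ]
    expect_equal(row$beta, f$beta, tolerance = 1e-10)
    expect_equal(row$se, f$se, tolerance = 1e-10)
    expect_equal(row$delta_pct, f$delta_pct, tolerance = 1e-10)
  }
  expect_true(all(scr$p_fdr >= scr$p_raw - 1e-12, na.rm = TRUE))

  # a constant assay is reported as failed without poisoning the others
  expr2 <- fx$expr
  expr2$log2_values[, 2] <- 1.23
  scr2 <- run_screening(expr2, fx$cohort)
  expect_identical(scr2$note[2], "degenerate fit")
  expect_true(is.na(scr2$p_raw[2]))
  expect_equal(scr2$beta[-2], scr$beta[-2], tolerance = 1e-12)
})

test_that("screening under the null is calibrated and strong signals reach FDR < 0.1", {
  fx <- make_screen_fixture(n = 300, n_assays = 200, seed = 21)
  scr <- run_screening(fx$expr, fx$cohort)
  frac <- mean(scr$p_raw < 0.05, na.rm = TRUE)
  se3 <- 3 * sqrt(0.05 * 0.95 / sum(!is.na(scr$p_raw)))
  expect_lt(abs(frac - 0.05), se3 + 1e-9)

  planted <- setNames(rep(beta_from_delta(-25, "log2"), 10),
                      sprintf("miR-%04d", 1:10))
  fy <- make_screen_fixture(n = 400, n_assays = 200, seed = 22,
                            planted = planted)
  scr2 <- run_screening(fy$expr, fy$cohort)
  hits <- scr2$assay[scr2$p_fdr < 0.1 & !is.na(scr2$p_fdr)]
  expect_true(all(names(planted) %in% hits))
})

test_that("select_top_k filters, orders by p with the documented tie rules", {
  scr <- data.frame(
    assay = c("a", "b", "c", "d", "e"),
    p_raw = c(0.01, 0.001, 0.01, 0.5, NA),
    delta_pct = c(2, 1, -5, 3, 4),
    expressed_frac = c(1, 1, 1, 0.3, 1),
    stringsAsFactors = FALSE
  )
  # tie at p=0.01: larger |delta| first; d fails the expressed gate; e failed fit
  expect_identical(select_top_k(scr, k = 3), c("b", "c", "a"))
  expect_warning(got <- select_top_k(scr, k = 10), "eligible")
  expect_identical(got, c("b", "c", "a"))
})

test_that("two-stage run validates planted assays and validated is a subset of top-k", {
  planted <- setNames(rep(beta_from_delta(-25, "log2"), 3),
                      sprintf("miR-%04d", 1:3))
  fs <- make_screen_fixture(n = 250, n_assays = 60, seed = 31, planted = planted)
  fv <- make_screen_fixture(n = 200, n_assays = 60, seed = 32, planted = planted)
  ts <- run_two_stage(fs$expr, fs$cohort, fv$expr, fv$cohort, k = 10)
  expect_true(all(ts$validated %in% ts$top_k))
  expect_true(all(names(planted) %in% ts$validated))
})

test_that("stratified fits equal manual subsetting and detect a planted interaction", {
  eff <- list(ev_cd14 = c(overweight = beta_from_delta(12.04, "ln"),
                          obese = beta_from_delta(1.51, "ln")))
  cfg <- generator_config(n_subjects = 1630, seed = 13, effect_table = eff)
  ex <- generate_exposure(cfg, n_days = 731, n_monitors = 5)
  co <- generate_cohort(cfg, ex)
  st <- stratified_and_interaction(co, model_spec("ev_cd14", "ln"))

  manual <- fit_adjusted(co[co$bmi_category == "overweight", ],
                         model_spec("ev_cd14", "ln",
                                    covariates = c("age", "sex", "smoking",
                                                   "app_temp_lag1")))
  expect_equal(st$overweight$beta, manual$beta, tolerance = 1e-12)
  expect_lt(st$p_interaction, 0.05)
  expect_error(
    stratified_and_interaction(co[co$bmi_category == "obese", ],
                               model_spec("ev_cd14", "ln")),
    "both BMI strata")
})
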