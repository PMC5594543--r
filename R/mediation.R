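#' Specification of a simple mediation model
#'
#' Single-mediator product-of-coefficients mediation: the mediator equation
#' regresses the (log2, normalized) miRNA M on PM10 and covariates; the
#' outcome equation regresses ln fibrinogen on PM10, M, and the same
#' covariates. The direct effect is the exposure slope of the outcome
#' equation, the indirect effect is the product of the exposure slope of
#' the mediator equation and the mediator slope of the outcome equation,
#' and for OLS on the same rows total = direct + indirect exactly.
#'
#' @param exposure PM10 lag column (X).
#' @param mediator mediator column (M).
#' @param outcome outcome column (Y); `"ln"` transform applied.
#' @param covariates adjustment covariates (shared by both equations).
#' @param n_boot bootstrap resamples for the interval (default 10000; a
#'   warning is issued below 1000, where the bias correction is unreliable).
#' @param ci_level confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @param ci_type `"bc"` (bias-corrected, the default) or `"percentile"`.
#' @return list of class `mediation_model_spec`.
#' @export
mediation_model_spec <- function(exposure = "pm10_lag1", mediator = NULL,
                                 outcome = "fibrinogen",
                                 covariates = c("age", "sex", "bmi",
                                                "smoking", "app_temp_lag1"),
                                 n_boot = 10000L, ci_level = 0.95,
                                 seed = 1L, ci_type = c("bc", "percentile")) {
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 1000L)
    warning("n_boot < 1000: bias-corrected intervals may be unreliable",
            call. = FALSE)
  check_scalar_number(ci_level, "ci_level", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  structure(list(exposure = exposure, mediator = mediator,
                 outcome = outcome, covariates = covariates,
                 n_boot = n_boot, ci_level = ci_level,
                 seed = check_count(seed, "seed", min = 0L),
                 ci_type = match.arg(ci_type)),
            class = "mediation_model_spec")
}

# Complete-case design matrices shared by both equations.
mediation_design <- function(data, spec) {
  pf <- prepare_model_frame(
    data, list(outcome = spec$outcome, exposure = spec$exposure,
               covariates = spec$covariates, stratum = NULL),
    extra = spec$mediator)
  df <- pf$df
  X0 <- stats::model.matrix(
    stats::reformulate(c(spec$exposure, spec$covariates)), data = df)
  list(
    X0 = X0, # intercept + exposure + covariates
    m = df[[spec$mediator]],
    y = transform_outcome(df[[spec$outcome]], "ln", spec$outcome),
    jx = match(spec$exposure, colnames(X0)),
    n_dropped = pf$n_dropped
  )
}

ols_coefs <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  coef <- numeric(ncol(X))
  coef[fit$pivot] <- fit$coefficients[seq_len(fit$rank)]
  coef
}

#' Point estimates for a simple mediation model
#'
#' Two OLS fits on the same complete-case rows plus the total-effect model
#' (Y on X without M). Verifies the linear decomposition identity
#' `total = direct + indirect` to 1e-8.
#'
#' @param data analysis data.frame.
#' @param spec a [mediation_model_spec()].
#' @return list of class `mediation_result` (point part): `beta_pm10`
#'   (X -> M), `gamma_m` (M -> Y), `direct`, `indirect`, `total`,
#'   `n_used`, `n_dropped`.
#' @export
fit_mediation <- function(data, spec) {
  d <- mediation_design(data, spec)
  Xy <- cbind(d$X0, mediator = d$m)
  c_m <- ols_coefs(d$X0, d$m)
  c_y <- ols_coefs(Xy, d$y)
  c_t <- ols_coefs(d$X0, d$y)
  if (is.null(c_m) || is.null(c_y) || is.null(c_t))
    stop_invalid("singular design in mediation model for mediator `%s`",
                 spec$mediator)
  beta_pm10 <- c_m[d$jx]
  gamma_m <- c_y[ncol(Xy)]
  direct <- c_y[d$jx]
  indirect <- beta_pm10 * gamma_m
  total <- c_t[d$jx]
  if (abs(total - direct - indirect) > 1e-8 * max(1, abs(total)))
    stop_invalid("mediation decomposition identity violated (numerical)")
  structure(list(mediator = spec$mediator, beta_pm10 = beta_pm10,
                 gamma_m = gamma_m, direct = direct, indirect = indirect,
                 total = total, n_used = nrow(d$X0),
                 n_dropped = d$n_dropped),
            class = "mediation_result")
}

# Order-statistic quantile with ceiling indexing: reproducible bit-for-bit.
boot_quantile <- function(sorted, p, B) {
  sorted[min(max(ceiling(p * B), 1L), B)]
}

#' Bias-corrected bootstrap interval from precomputed draws
#'
#' Given B bootstrap estimates of the indirect effect and the point
#' estimate, computes `z0 = qnorm(#\{theta* < theta_hat\}/B)` with ties
#' counted half, and returns the empirical quantiles (ceiling-indexed order
#' statistics) at `pnorm(2 z0 + z_(alpha/2))` and `pnorm(2 z0 +
#' z_(1-alpha/2))`. Bias-corrected without acceleration. A bootstrap
#' distribution exactly symmetric about the point estimate gives `z0 = 0`
#' and the plain percentile interval; a degenerate distribution (all draws
#' identical) is an error; an empty tail clamps `z0` with a warning.
#'
#' @param theta_boot numeric vector of bootstrap estimates.
#' @param theta_hat point estimate.
#' @param ci_level confidence level.
#' @param ci_type `"bc"` or `"percentile"`.
#' @return numeric `c(low, high)`.
#' @export
bc_interval <- function(theta_boot, theta_hat, ci_level = 0.95,
                        ci_type = c("bc", "percentile")) {
  ci_type <- match.arg(ci_type)
  theta_boot <- theta_boot[is.finite(theta_boot)]
  B <- length(theta_boot)
  if (B < 2L || stats::sd(theta_boot) == 0)
    stop_invalid("degenerate bootstrap distribution of the indirect effect")
  alpha <- 1 - ci_level
  srt <- sort(theta_boot)
  if (ci_type == "percentile") {
    return(c(boot_quantile(srt, alpha / 2, B),
             boot_quantile(srt, 1 - alpha / 2, B)))
  }
  frac <- (sum(theta_boot < theta_hat) + 0.5 * sum(theta_boot == theta_hat)) / B
  if (frac <= 0 || frac >= 1) {
    warning("all bootstrap estimates on one side of the point estimate; z0 clamped",
            call. = FALSE)
    frac <- min(max(frac, 1 / B), 1 - 1 / B)
  }
  z0 <- stats::qnorm(frac)
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  c(boot_quantile(srt, stats::pnorm(2 * z0 + zlo), B),
    boot_quantile(srt, stats::pnorm(2 * z0 + zhi), B))
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Nonparametric pairs bootstrap: whole subject rows (X, M, Y, covariates
#' jointly) are resampled with replacement `n_boot` times; each resample
#' refits both equations and records the product of coefficients. Seeded
#' and fully reproducible. Resamples with a singular design (e.g. a factor
#' level dropped) are discarded and counted.
#'
#' @param data analysis data.frame.
#' @param spec a [mediation_model_spec()].
#' @return list with `ci` (low, high), `theta_boot`, `n_bad` (discarded
#'   resamples).
#' @export
bc_bootstrap_ci <- function(data, spec) {
  d <- mediation_design(data, spec)
  point <- fit_mediation(data, spec)
  n <- nrow(d$X0)
  Xy <- cbind(d$X0, mediator = d$m)
  jm <- ncol(Xy)
  theta <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cm <- ols_coefs(d$X0[idx, , drop = FALSE], d$m[idx])
      cy <- ols_coefs(Xy[idx, , drop = FALSE], d$y[idx])
      if (is.null(cm) || is.null(cy)) return(NA_real_)
      cm[d$jx] * cy[jm]
    }, 0)
  })
  n_bad <- sum(!is.finite(theta))
  ci <- bc_interval(theta, point$indirect, spec$ci_level, spec$ci_type)
  list(ci = ci, theta_boot = theta, n_bad = n_bad)
}

#' Mediation analysis over a panel of candidate mediators
#'
#' One simple mediation model per candidate: point estimates, BC bootstrap
#' interval for the indirect effect, and a mediated flag (interval excludes
#' zero). Per-mediator RNG streams derive deterministically from the master
#' seed and the mediator id, so results do not depend on list order.
#'
#' @param data analysis data.frame.
#' @param mediators character vector of mediator column names.
#' @param spec a [mediation_model_spec()] template (its `mediator` field is
#'   overridden per candidate).
#' @return data.frame of class `mediation_panel`: mediator, beta_pm10,
#'   gamma_m, direct, indirect, total, ci_low, ci_high, mediated, n_used,
#'   n_boot, seed, note. Per-mediator failures are isolated into `note`
#'   rows rather than aborting the panel.
#' @export
run_mediation_panel <- function(data, mediators, spec) {
  if (!length(mediators)) {
    out <- data.frame(mediator = character(), beta_pm10 = numeric(),
                      gamma_m = numeric(), direct = numeric(),
                      indirect = numeric(), total = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      mediated = logical(), n_used = integer(),
                      n_boot = integer(), seed = integer(),
                      note = character(), stringsAsFactors = FALSE)
    class(out) <- c("mediation_panel", "data.frame")
    return(out)
  }
  rows <- lapply(mediators, function(md) {
    sp <- spec
    sp$mediator <- md
    sp$seed <- string_seed(spec$seed, md)
    tryCatch({
      pt <- fit_mediation(data, sp)
      bt <- bc_bootstrap_ci(data, sp)
      data.frame(mediator = md, beta_pm10 = pt$beta_pm10,
                 gamma_m = pt$gamma_m, direct = pt$direct,
                 indirect = pt$indirect, total = pt$total,
                 ci_low = bt$ci[1L], ci_high = bt$ci[2L],
                 mediated = bt$ci[1L] > 0 || bt$ci[2L] < 0,
                 n_used = pt$n_used, n_boot = sp$n_boot, seed = sp$seed,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(mediator = md, beta_pm10 = NA_real_, gamma_m = NA_real_,
                 direct = NA_real_, indirect = NA_real_, total = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, mediated = NA,
                 n_used = NA_integer_, n_boot = sp$n_boot, seed = sp$seed,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mediation_panel", "data.frame")
  out
}
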