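#' Parameter-recovery scenarios
#'
#' Each function here defines one simulate-then-reanalyze scenario: the
#' generator plants a known percent change per 10 ug/m3 as ground truth,
#' the corresponding analysis stage is run exactly as it would be on real
#' data, and the recovered percent change is returned, one value per
#' seeded replicate. These scenarios are the package's calibration
#' evidence: an unbiased pipeline recovers the planted value up to
#' Monte-Carlo error.
#'
#' @name recovery
#' @keywords internal
NULL

scenario_exposure <- function(config, n_days = 731L, n_monitors = 5L) {
  generate_exposure(config, n_days = n_days, n_monitors = n_monitors)
}

#' Recover a planted EV-count effect
#'
#' Plants an ln-scale Day -1 (or yearly-average) PM10 slope on one EV
#' outcome, simulates cohorts, and refits the adjusted association model
#' (age, sex, BMI, smoking, apparent temperature).
#'
#' @param delta_true planted percent change per 10 ug/m3.
#' @param outcome EV outcome name (e.g. `"ev_nta"`).
#' @param exposure `"pm10_lag1"` (short-term) or `"pm10_1yr"` (long-term).
#' @param n_subjects cohort size per replicate.
#' @param n_reps number of seeded replicates.
#' @param base_seed replicate r uses seed `base_seed + r`.
#' @return Numeric vector of recovered percent changes, one per replicate.
#' @export
recover_ev_effect <- function(delta_true, outcome = "ev_nta",
                              exposure = "pm10_lag1", n_subjects = 1630L,
                              n_reps = 20L, base_seed = 0L) {
  beta <- beta_from_delta(delta_true, "ln")
  effect <- stats::setNames(list(beta), outcome)
  vapply(seq_len(n_reps), function(r) {
    cfg <- if (exposure == "pm10_1yr")
      generator_config(n_subjects = n_subjects, seed = base_seed + r,
                       longterm_effect_table = effect)
    else
      generator_config(n_subjects = n_subjects, seed = base_seed + r,
                       effect_table = effect)
    cohort <- generate_cohort(cfg, scenario_exposure(cfg))
    fit_adjusted(cohort, model_spec(outcome, "ln", exposure))$delta_pct
  }, 0)
}

#' Recover a BMI-stratum-specific EV effect
#'
#' Plants different ln-scale slopes in the overweight and obese strata,
#' refits the stratified models (BMI dropped from covariates) and the
#' pooled interaction model.
#'
#' @param delta_overweight,delta_obese planted percent changes per
#'   10 ug/m3 by stratum.
#' @param outcome EV outcome name.
#' @inheritParams recover_ev_effect
#' @return data.frame with one row per replicate: `delta_overweight`,
#'   `delta_obese`, `p_interaction`.
#' @export
recover_stratified_effect <- function(delta_overweight, delta_obese,
                                      outcome = "ev_cd14",
                                      n_subjects = 1630L, n_reps = 20L,
                                      base_seed = 0L) {
  effect <- stats::setNames(list(c(
    overweight = beta_from_delta(delta_overweight, "ln"),
    obese = beta_from_delta(delta_obese, "ln"))), outcome)
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- generator_config(n_subjects = n_subjects, seed = base_seed + r,
                            effect_table = effect)
    cohort <- generate_cohort(cfg, scenario_exposure(cfg))
    st <- stratified_and_interaction(cohort, model_spec(outcome, "ln"))
    data.frame(delta_overweight = st$overweight$delta_pct,
               delta_obese = st$obese$delta_pct,
               p_interaction = st$p_interaction)
  })
  do.call(rbind, rows)
}

# Validation-phase panel: 40 custom assays + 4 controls, no never-amplified
# assays, control-pair normalization.
validation_config <- function(n_subjects, seed, ...) {
  generator_config(n_subjects = n_subjects, n_assays = 40L,
                   frac_never_amplified = 0, seed = seed, ...)
}

validation_expression <- function(cfg, cohort, panel = NULL) {
  panel <- panel %||% generate_crt_panel(cfg, cohort)
  qc <- apply_qc(panel, qc_config())
  kept <- drop_never_amplified(qc)$panel
  normalize_expression(kept, normalizer_control_pair())
}

#' Recover a planted log2-scale miRNA effect
#'
#' Plants a log2-scale Day -1 PM10 slope on one panel assay, simulates
#' validation-style cohorts (40-assay custom panel, endogenous + exogenous
#' control normalization), and refits the adjusted per-assay model.
#'
#' @param delta_true planted percent change per 10 ug/m3 (log2 scale).
#' @inheritParams recover_ev_effect
#' @return Numeric vector of recovered percent changes.
#' @export
recover_mirna_effect <- function(delta_true, n_subjects = 747L,
                                 n_reps = 20L, base_seed = 0L) {
  beta <- beta_from_delta(delta_true, "log2")
  vapply(seq_len(n_reps), function(r) {
    cfg <- validation_config(n_subjects, base_seed + r,
                             assay_effects = c("miR-0001" = beta))
    cohort <- generate_cohort(cfg, scenario_exposure(cfg))
    expr <- validation_expression(cfg, cohort)
    scr <- run_screening(expr, cohort, assays = "miR-0001")
    scr$delta_pct[1L]
  }, 0)
}

# Shared planting for the fibrinogen/mediation scenarios: five mediators
# carrying equal shares of the indirect path.
mediated_fibrinogen_config <- function(n_subjects, seed, delta_total,
                                       frac_direct = 0.5,
                                       mediator_delta = -15,
                                       n_mediators = 5L,
                                       n_null_candidates = 0L,
                                       gamma_each = NULL) {
  beta_m <- beta_from_delta(mediator_delta, "log2")
  if (is.null(gamma_each)) {
    total <- beta_from_delta(delta_total, "ln")
    gamma_each <- (1 - frac_direct) * total / n_mediators / beta_m
    gamma_pm10 <- frac_direct * total
  } else {
    # explicit paths: the direct share mirrors the summed indirect path
    gamma_pm10 <- n_mediators * beta_m * gamma_each *
      frac_direct / (1 - frac_direct)
  }
  meds <- lapply(seq_len(n_mediators), function(j)
    list(assay = sprintf("miR-%04d", j), beta = beta_m, gamma = gamma_each))
  nulls <- if (n_null_candidates > 0L)
    stats::setNames(rep(0, n_null_candidates),
                    sprintf("miR-%04d", n_mediators + seq_len(n_null_candidates)))
  else numeric()
  validation_config(n_subjects, seed, mediation_spec = meds,
                    gamma_pm10 = gamma_pm10, assay_effects = nulls)
}

#' Recover a planted total fibrinogen effect
#'
#' Plants a total PM10 -> ln fibrinogen effect routed partly through
#' mediating miRNAs (direct share `frac_direct`, the rest split equally
#' over five mediators), then fits the total-effect model: ln(fibrinogen)
#' on PM10 and covariates, without mediators.
#'
#' @param delta_total planted total percent change per 10 ug/m3.
#' @param frac_direct share of the total carried by the direct path.
#' @inheritParams recover_ev_effect
#' @return Numeric vector of recovered total percent changes.
#' @export
recover_fibrinogen_total <- function(delta_total, frac_direct = 0.5,
                                     n_subjects = 1630L, n_reps = 20L,
                                     base_seed = 0L) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- mediated_fibrinogen_config(n_subjects, base_seed + r, delta_total,
                                      frac_direct = frac_direct)
    exposure <- scenario_exposure(cfg)
    cohort <- generate_cohort(cfg, exposure)
    panel <- generate_crt_panel(cfg, cohort)
    cohort <- plant_mediation(cfg, cohort, panel)
    fit_adjusted(cohort, model_spec("fibrinogen", "ln"))$delta_pct
  }, 0)
}

#' Mediated-flag counts over replicates
#'
#' Nine candidate mediators, five with strong planted two-path effects
#' (Delta% = -15 per 10 ug/m3 on the mediator path, gamma = -0.04 on ln
#' fibrinogen, giving per-path z-scores well above detection thresholds at
#' n = 747) and four fully null; per replicate the mediation panel runs
#' with a BC bootstrap of `n_boot` resamples and the number of mediated
#' flags is recorded. This is a power/specificity scenario, not a
#' reproduction of any observed effect size.
#'
#' @param n_boot bootstrap resamples per mediator.
#' @inheritParams recover_ev_effect
#' @return Integer vector: mediated-flag count per replicate.
#' @export
mediation_count_replicates <- function(n_reps = 20L, n_subjects = 747L,
                                       n_boot = 1000L, base_seed = 0L) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- mediated_fibrinogen_config(n_subjects, base_seed + r,
                                      delta_total = NULL,
                                      frac_direct = 0.5,
                                      n_null_candidates = 4L,
                                      gamma_each = -0.04)
    exposure <- scenario_exposure(cfg)
    cohort <- generate_cohort(cfg, exposure)
    panel <- generate_crt_panel(cfg, cohort)
    cohort <- plant_mediation(cfg, cohort, panel)
    expr <- validation_expression(cfg, cohort, panel)
    cand <- sprintf("miR-%04d", 1:9)
    dat <- cohort
    for (md in cand) dat[[md]] <- expr$log2_values[, md]
    suppressWarnings(
      pan <- run_mediation_panel(
        dat, cand,
        mediation_model_spec(n_boot = n_boot, seed = base_seed + r))
    )
    sum(pan$mediated, na.rm = TRUE)
  }, 0L)
}

#' QC fixture counts: the exact-cleaning scenario
#'
#' Builds a seeded screening panel of 754 assays with exactly 209 rendered
#' unamplified in every subject, applies the Crt/AmpScore rule and the
#' never-amplified exclusion, and returns the counts.
#'
#' @param seed generator seed.
#' @param n_subjects panel depth (enough that no additional assay is
#'   coincidentally unamplified in all subjects).
#' @return list: `n_input` (miRNA assays on the panel), `n_dropped`,
#'   `n_retained` (miRNA assays surviving the exclusion).
#' @export
qc_fixture_counts <- function(seed = 1L, n_subjects = 300L) {
  cfg <- generator_config(n_subjects = n_subjects, n_assays = 754L,
                          frac_never_amplified = 209 / 754, seed = seed)
  exposure <- scenario_exposure(cfg)
  cohort <- generate_cohort(cfg, exposure)
  panel <- generate_crt_panel(cfg, cohort)
  qc <- apply_qc(panel, qc_config())
  res <- drop_never_amplified(qc)
  mir_in <- setdiff(panel$assay_ids, panel$control_ids)
  mir_kept <- setdiff(res$panel$assay_ids, res$panel$control_ids)
  list(n_input = length(mir_in),
       n_dropped = length(intersect(res$dropped, mir_in)),
       n_retained = length(mir_kept))
}
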