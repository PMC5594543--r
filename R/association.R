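#' Model specification for adjusted association fits
#'
#' Declares the outcome (with its transform), the exposure column, the
#' adjustment covariates, and optionally a BMI-category interaction or a
#' single-stratum restriction. The default covariate set is the a priori
#' adjustment used throughout: age, sex, BMI, smoking status and the Day -1
#' apparent temperature. Stratified fits drop BMI from the covariates.
#'
#' @param outcome outcome column name.
#' @param transform one of `"ln"`, `"log2"`, `"none"`.
#' @param exposure exposure column name (PM10, ug/m3; slopes are per
#'   1 ug/m3 and the x10 scaling lives only in [delta_pct()]).
#' @param covariates character vector of covariate columns.
#' @param interaction logical: add `bmi_category * exposure` to the model.
#' @param stratum optional `"overweight"` or `"obese"` restriction.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, transform = c("ln", "log2", "none"),
                       exposure = "pm10_lag1",
                       covariates = c("age", "sex", "bmi", "smoking",
                                      "app_temp_lag1"),
                       interaction = FALSE, stratum = NULL) {
  transform <- match.arg(transform)
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, c("overweight", "obese"))
    covariates <- setdiff(covariates, "bmi")
  }
  structure(list(outcome = outcome, transform = transform,
                 exposure = exposure, covariates = covariates,
                 interaction = isTRUE(interaction), stratum = stratum),
            class = "model_spec")
}

transform_outcome <- function(y, transform, outcome) {
  if (transform == "none") return(y)
  if (any(y[is.finite(y)] <= 0))
    stop_invalid("outcome `%s` must be positive for a %s transform",
                 outcome, transform)
  switch(transform, ln = log(y), log2 = log2(y))
}

# Categorical covariates enter as indicator contrasts with the reference
# level chosen first alphabetically (deterministic across inputs).
prepare_model_frame <- function(data, spec, extra = character()) {
  cols <- unique(c(spec$outcome, spec$exposure, spec$covariates, extra))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop_invalid("column(s) not in data: %s", paste(missing_cols, collapse = ", "))
  df <- data[, cols, drop = FALSE]
  if (!is.null(spec$stratum)) {
    if (!"bmi_category" %in% names(data))
      stop_invalid("stratified fit needs a `bmi_category` column")
    df <- df[data$bmi_category == spec$stratum, , drop = FALSE]
  }
  for (nm in names(df)) {
    if (is.character(df[[nm]]))
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
  }
  cc <- stats::complete.cases(df)
  list(df = df[cc, , drop = FALSE], n_dropped = sum(!cc))
}

#' Adjusted linear association fit with percent-change effect
#'
#' Ordinary-least-squares fit of the transformed outcome on the exposure and
#' covariates, complete cases only (dropped-row count reported). Returns the
#' exposure slope per 1 ug/m3, its standard error, the two-sided t-test
#' p-value, and the percent change per 10 ug/m3 with a Wald confidence
#' interval mapped monotonically to the percent scale.
#'
#' @param data joined cohort + exposure data.frame.
#' @param spec a [model_spec()].
#' @param ci_level confidence level for the interval (default 0.95).
#' @return list of class `association_result`: `outcome`, `beta`, `se`,
#'   `p_raw`, `delta_pct`, `ci_low_pct`, `ci_high_pct`, `n_used`,
#'   `n_dropped`, `transform`, plus the underlying `fit`.
#' @export
fit_adjusted <- function(data, spec, ci_level = 0.95) {
  pf <- prepare_model_frame(data, spec)
  df <- pf$df
  p_needed <- 2L + length(spec$covariates)
  if (nrow(df) < p_needed + 2L)
    stop_invalid("not enough complete rows (%d) for the model", nrow(df))
  df$.y <- transform_outcome(df[[spec$outcome]], spec$transform, spec$outcome)
  rhs <- c(spec$exposure, spec$covariates)
  if (spec$interaction)
    rhs <- c(rhs, sprintf("bmi_category * %s", spec$exposure))
  fml <- stats::reformulate(rhs, response = ".y")
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_invalid("singular design: collinear column(s) %s",
                 paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm[spec$exposure, 1L]
  se <- sm[spec$exposure, 2L]
  p <- sm[spec$exposure, 4L]
  zq <- stats::qt(1 - (1 - ci_level) / 2, df = fit$df.residual)
  ci <- beta + c(-1, 1) * zq * se
  dp <- if (spec$transform == "none") rep(NA_real_, 3) else
    delta_pct(c(beta, ci), spec$transform)
  structure(list(
    outcome = spec$outcome, exposure = spec$exposure,
    transform = spec$transform, stratum = spec$stratum,
    beta = beta, se = se, p_raw = p,
    delta_pct = dp[1L], ci_low_pct = dp[2L], ci_high_pct = dp[3L],
    n_used = nrow(df), n_dropped = pf$n_dropped, fit = fit
  ), class = "association_result")
}

#' Percent change per 10 ug/m3 from a per-unit slope
#'
#' `(exp(10 beta) - 1) * 100` for ln-scale outcomes and
#' `(2^(10 beta) - 1) * 100` for log2-scale outcomes. [beta_from_delta()] is
#' the exact inverse, used to plant generator truths from printed percent
#' changes.
#'
#' @param beta slope per 1 ug/m3 on the transformed scale (vectorized).
#' @param transform `"ln"` or `"log2"`.
#' @return Percent change per 10 ug/m3.
#' @export
delta_pct <- function(beta, transform = c("ln", "log2")) {
  transform <- match.arg(transform)
  if (any(!is.finite(beta))) stop_invalid("`beta` must be finite")
  base <- switch(transform, ln = exp(1), log2 = 2)
  (base^(10 * beta) - 1) * 100
}

#' @rdname delta_pct
#' @param delta percent change per 10 ug/m3.
#' @export
beta_from_delta <- function(delta, transform = c("ln", "log2")) {
  transform <- match.arg(transform)
  log(delta / 100 + 1, base = switch(transform, ln = exp(1), log2 = 2)) / 10
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), with input
#' validation; delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-assay screening of an expression matrix against PM10
#'
#' One adjusted fit per assay of log2 expression on the exposure and
#' covariates, vectorized through a shared design matrix (all assays share
#' complete cases because unamplified wells carry the floor value, not
#' `NA`). BH adjustment runs across all successfully tested assays; an assay
#' whose fit fails (e.g. constant expression) is reported with `NA`
#' statistics and does not abort the run. Per-row equality with
#' [fit_adjusted()] is exact.
#'
#' @param expr an `expression_matrix` (log2 values are used).
#' @param data cohort + exposure data.frame aligned with the panel subjects.
#' @param spec a [model_spec()] template; its `outcome` field is ignored.
#' @param assays assay ids to test (default: all non-control assays).
#' @param ci_level Wald CI level.
#' @return data.frame of class `screening_result`: assay, beta, se, p_raw,
#'   delta_pct, ci_low_pct, ci_high_pct, p_fdr, expressed_frac, n_used,
#'   note.
#' @export
run_screening <- function(expr, data, spec = model_spec("expr", "log2"),
                          assays = NULL, ci_level = 0.95) {
  stopifnot(inherits(expr, "expression_matrix"))
  assays <- assays %||% setdiff(expr$assay_ids, expr$control_ids)
  pf <- prepare_model_frame(data, list(outcome = spec$exposure,
                                       exposure = spec$exposure,
                                       covariates = spec$covariates,
                                       stratum = NULL),
                            extra = "subject_id")
  df <- pf$df
  keep <- match(as.character(df$subject_id), rownames(expr$log2_values))
  if (anyNA(keep))
    stop_invalid("expression matrix rows do not match data subjects")
  Y <- expr$log2_values[keep, assays, drop = FALSE]
  X <- stats::model.matrix(
    stats::reformulate(c(spec$exposure, spec$covariates)), data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_invalid("singular screening design")
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  dfree <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dfree
  xtxi <- chol2inv(chol(crossprod(X)))
  jx <- match(spec$exposure, colnames(X))
  beta <- coefs[jx, ]
  se <- sqrt(s2 * xtxi[jx, jx])
  # relative residual floor: an (near-)exactly fitted column, e.g. constant
  # expression, has no usable error estimate
  ok <- is.finite(beta) & is.finite(se) &
    s2 > 1e-16 * pmax(1, colMeans(Y * Y))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), dfree, lower.tail = FALSE)
  zq <- stats::qt(1 - (1 - ci_level) / 2, dfree)
  dp <- delta_pct(beta[ok], spec$transform)
  lo <- delta_pct(beta[ok] - zq * se[ok], spec$transform)
  hi <- delta_pct(beta[ok] + zq * se[ok], spec$transform)
  out <- data.frame(
    assay = assays, beta = beta, se = se, p_raw = p,
    delta_pct = NA_real_, ci_low_pct = NA_real_, ci_high_pct = NA_real_,
    p_fdr = NA_real_,
    expressed_frac = colMeans(expr$expressed[keep, assays, drop = FALSE]),
    n_used = nrow(df),
    note = ifelse(ok, "", "degenerate fit"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$delta_pct[ok] <- dp
  out$ci_low_pct[ok] <- lo
  out$ci_high_pct[ok] <- hi
  out$p_raw[!ok] <- NA_real_
  out$beta[!ok] <- NA_real_
  out$se[!ok] <- NA_real_
  out$p_fdr[ok] <- bh_fdr(out$p_raw[ok])
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Select the top-k assays for validation
#'
#' Filters to assays expressed in at least `expressed_min` of subjects,
#' orders by ascending raw p (ties by descending `|delta_pct|`, then assay
#' id), and takes the first `k`. Fewer than `k` eligible assays returns the
#' whole eligible set with a warning.
#'
#' @param screening a `screening_result`.
#' @param k number of assays to carry forward (default 40).
#' @param expressed_min candidacy gate on expressed fraction (default 0.5,
#'   inclusive).
#' @return Character vector of assay ids.
#' @export
select_top_k <- function(screening, k = 40L, expressed_min = 0.5) {
  el <- screening[!is.na(screening$p_raw) &
                    screening$expressed_frac >= expressed_min, , drop = FALSE]
  ord <- order(el$p_raw, -abs(el$delta_pct), el$assay)
  el <- el[ord, , drop = FALSE]
  if (nrow(el) < k) {
    warning(sprintf("only %d eligible assays for top-%d selection",
                    nrow(el), k), call. = FALSE)
    return(el$assay)
  }
  el$assay[seq_len(k)]
}

#' Two-stage screening / validation analysis
#'
#' Stage 1 screens all assays in the discovery set (BH FDR across assays,
#' candidacy = FDR p below `fdr_threshold` and expressed in at least half
#' the subjects); the top `k` candidates by raw p are then refit in the
#' independent validation set, where raw p < `validation_alpha` declares an
#' assay differentially expressed.
#'
#' @param expr_screen,data_screen expression matrix and covariate data of
#'   the discovery subset.
#' @param expr_valid,data_valid same for the validation subset.
#' @param spec a [model_spec()] template.
#' @param k top-k carried to validation.
#' @param fdr_threshold screening FDR threshold (default 0.1).
#' @param validation_alpha validation raw-p threshold (default 0.05).
#' @return list of class `two_stage_result`: `screening`, `top_k`,
#'   `validation`, `validated` (assay ids).
#' @export
run_two_stage <- function(expr_screen, data_screen, expr_valid, data_valid,
                          spec = model_spec("expr", "log2"), k = 40L,
                          fdr_threshold = 0.1, validation_alpha = 0.05) {
  screening <- run_screening(expr_screen, data_screen, spec)
  top <- select_top_k(screening, k = k)
  validation <- run_screening(expr_valid, data_valid, spec,
                              assays = intersect(top, expr_valid$assay_ids))
  # validation-stage BH is across the k refits, kept for reporting only
  validated <- validation$assay[!is.na(validation$p_raw) &
                                  validation$p_raw < validation_alpha]
  structure(list(screening = screening, top_k = top,
                 validation = validation, validated = validated,
                 fdr_threshold = fdr_threshold,
                 validation_alpha = validation_alpha),
            class = "two_stage_result")
}

#' BMI-stratified fits with an interaction test
#'
#' Fits the exposure model separately in the overweight and obese strata
#' (dropping BMI from the covariates) and, in the pooled data, a model with
#' a `bmi_category x exposure` product term whose Wald p-value is the
#' interaction test.
#'
#' @param data cohort + exposure data.frame with `bmi_category`.
#' @param spec a [model_spec()] (its `stratum`/`interaction` fields are
#'   managed internally).
#' @return list of class `stratified_result`: `overweight`, `obese`
#'   (association results), `p_interaction`.
#' @export
stratified_and_interaction <- function(data, spec) {
  strata <- unique(data$bmi_category)
  if (!all(c("overweight", "obese") %in% strata))
    stop_invalid("interaction undefined: need both BMI strata in the data")
  fits <- lapply(c(overweight = "overweight", obese = "obese"), function(s)
    fit_adjusted(data, model_spec(spec$outcome, spec$transform,
                                  spec$exposure, spec$covariates,
                                  stratum = s)))
  pooled_spec <- model_spec(spec$outcome, spec$transform, spec$exposure,
                            c(setdiff(spec$covariates, "bmi"),
                              "bmi_category"),
                            interaction = TRUE)
  pooled <- fit_adjusted(data, pooled_spec)
  cf <- summary(pooled$fit)$coefficients
  ix <- grep(paste0("bmi_category.*:", pooled_spec$exposure), rownames(cf))
  if (!length(ix))
    ix <- grep(paste0(pooled_spec$exposure, ":bmi_category"), rownames(cf))
  structure(list(overweight = fits$overweight, obese = fits$obese,
                 p_interaction = unname(cf[ix[1L], 4L]), pooled = pooled),
            class = "stratified_result")
}

#' Flatten association results to a table
#'
#' @param results a list of `association_result` objects.
#' @return data.frame with one row per result (the `fit` objects dropped).
#' @export
association_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(outcome = r$outcome, exposure = r$exposure,
               stratum = r$stratum %||% "all",
               transform = r$transform, beta = r$beta, se = r$se,
               p_raw = r$p_raw, delta_pct = r$delta_pct,
               ci_low_pct = r$ci_low_pct, ci_high_pct = r$ci_high_pct,
               n_used = r$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
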