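# Shared fixture builders; everything is generated in code at test time.

# Minimal crt_panel from explicit matrices.
make_panel <- function(crt, ampscore = NULL, control_ids = character()) {
  if (is.null(ampscore)) ampscore <- matrix(2, nrow(crt), ncol(crt))
  dimnames(ampscore) <- dimnames(crt)
  structure(list(crt = crt, ampscore = ampscore,
                 assay_ids = colnames(crt), control_ids = control_ids,
                 subject_ids = rownames(crt),
                 never_amplified = character()),
            class = "crt_panel")
}

named_matrix <- function(values, n_sub, n_assay, assay_prefix = "A") {
  m <- matrix(values, n_sub, n_assay)
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_sub)),
                      sprintf("%s%02d", assay_prefix, seq_len(n_assay)))
  m
}

# Hand-built exposure series: one row per monitor-day with explicit values.
make_series <- function(monitors, daily) {
  structure(list(monitors = monitors, daily = daily),
            class = "exposure_series")
}

flat_series <- function(values_by_monitor, dates,
                        coords = list(c(0, 0), c(10, 0))) {
  mon <- data.frame(
    monitor_id = names(values_by_monitor),
    x = vapply(coords[seq_along(values_by_monitor)], `[`, 0, 1L),
    y = vapply(coords[seq_along(values_by_monitor)], `[`, 0, 2L),
    stringsAsFactors = FALSE
  )
  daily <- do.call(rbind, lapply(names(values_by_monitor), function(id) {
    v <- values_by_monitor[[id]]
    data.frame(monitor_id = id, date = dates,
               pm10 = rep_len(v, length(dates)),
               temperature = 15, rh = 60, stringsAsFactors = FALSE)
  }))
  make_series(mon, daily)
}

subject_row <- function(id = "S1", xy = c(1, 0), date = as.Date("2020-02-01")) {
  data.frame(subject_id = id, res_x = xy[1], res_y = xy[2],
             enrollment_date = date, stringsAsFactors = FALSE)
}

# Small cohort-like analysis table with purely synthetic regressors, for
# model-level tests that do not need the full generator.
make_analysis_df <- function(n, seed = 1, beta = 0, sigma = 0.3,
                             transform = "ln") {
  set.seed(seed)
  pm <- rlnorm(n, log(40), 0.4)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    pm10_lag1 = pm,
    age = rnorm(n, 52, 14),
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.73, 0.27)),
    bmi = runif(n, 25, 45),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    app_temp_lag1 = rnorm(n, 12, 8),
    stringsAsFactors = FALSE
  )
  lny <- 5 + beta * pm + 0.002 * df$age + 0.03 * (df$sex == "F") +
    rnorm(n, 0, sigma)
  df$y <- if (transform == "ln") exp(lny) else 2^lny
  df
}
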