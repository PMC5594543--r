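test_that("nearest_monitor minimizes distance, breaks ties by id, matches brute force", {
  one <- data.frame(monitor_id = "M1", x = 5, y = 5)
  expect_identical(nearest_monitor(c(0, 0), one), "M1")

  # equidistant pair: lower id wins
  two <- data.frame(monitor_id = c("B", "A"), x = c(-1, 1), y = c(0, 0))
  expect_identical(nearest_monitor(c(0, 0), two), "A")

  set.seed(42)
  mons <- data.frame(monitor_id = sprintf("M%02d", 1:50),
                     x = runif(50, 0, 100), y = runif(50, 0, 100))
  for (k in 1:25) {
    p <- runif(2, 0, 100)
    d <- sqrt((mons$x - p[1])^2 + (mons$y - p[2])^2)
    expect_identical(nearest_monitor(p, mons),
                     mons$monitor_id[which.min(d)])
  }
  expect_error(nearest_monitor(c(0, 0), mons[0, ]), "non-empty")
})

test_that("grid-cell assignment follows the half-open convention and brute force", {
  origin <- c(100, 200)
  expect_identical(assign_grid_cell(origin, origin, 4, c(10, 10)),
                   c(0L, 0L))
  # interior boundary point goes to the higher-index cell
  expect_identical(assign_grid_cell(c(104, 202), origin, 4, c(10, 10)),
                   c(1L, 0L))
  expect_error(assign_grid_cell(c(99, 200), origin, 4, c(10, 10)),
               "outside the grid")
  set.seed(7)
  for (k in 1:100) {
    p <- origin + runif(2, 0, 39.99)
    got <- assign_grid_cell(p, origin, 4, c(10, 10))
    # brute-force point-in-rectangle scan
    hit <- NULL
    for (ix in 0:9) for (iy in 0:9) {
      lo <- origin + 4 * c(ix, iy)
      if (p[1] >= lo[1] && p[1] < lo[1] + 4 && p[2] >= lo[2] && p[2] < lo[2] + 4)
        hit <- c(ix, iy)
    }
    expect_identical(got, as.integer(hit))
  }
})

test_that("apparent temperature: saturation limit, oracle value, monotone in humidity", {
  t <- c(-5, 0, 10, 20, 30)
  expect_equal(apparent_temperature(t, 100), -2.653 + 0.994 * t + 0.0153 * t^2,
               tolerance = 1e-10)

  # independently coded Magnus + Steadman oracle
  oracle_at <- function(ta, rh) {
    gamma <- log(rh / 100) + (17.625 * ta) / (243.04 + ta)
    td <- 243.04 * gamma / (17.625 - gamma)
    -2.653 + 0.994 * ta + 0.0153 * td * td
  }
  expect_equal(apparent_temperature(20, 50), oracle_at(20, 50), tolerance = 1e-12)
  expect_equal(apparent_temperature(31.5, 83), oracle_at(31.5, 83), tolerance = 1e-12)

  # monotone nondecreasing in humidity wherever the dew point is >= 0 degC
  # (below that the quadratic dew-point term turns around)
  for (ta in c(10, 15, 25, 35)) {
    rh_floor <- 100 * exp(-17.625 * ta / (243.04 + ta))
    at <- apparent_temperature(rep(ta, 50),
                               seq(rh_floor + 0.5, 100, length.out = 50))
    expect_true(all(diff(at) >= -1e-12))
  }
  expect_error(apparent_temperature(20, 101), "rh")
  expect_error(apparent_temperature(20, -1), "rh")
})

test_that("lag assignment: constant series, reversed window, clinic vs residence", {
  dates <- seq(as.Date("2020-01-01"), by = 1, length.out = 40)
  s_const <- flat_series(list(M1 = 33), dates)
  r <- assign_lags(subject_row(date = dates[20]), s_const, c(0, 0),
                   longterm = FALSE)
  expect_equal(unlist(r[paste0("pm10_lag", 0:7)], use.names = FALSE),
               rep(33, 8))

  # distinct value per day: lag vector is the reversed 8-day window
  vals <- seq_along(dates) * 10
  s_days <- make_series(
    data.frame(monitor_id = "M1", x = 0, y = 0),
    data.frame(monitor_id = "M1", date = dates, pm10 = vals,
               temperature = 15, rh = 60, stringsAsFactors = FALSE))
  r <- assign_lags(subject_row(date = dates[20]), s_days, c(0, 0),
                   longterm = FALSE)
  expect_equal(unlist(r[paste0("pm10_lag", 0:7)], use.names = FALSE),
               rev(vals[13:20]))

  # two monitors with constants a, b: Day 0 from clinic monitor, rest residence
  s2 <- flat_series(list(M1 = 11, M2 = 77), dates)
  r <- assign_lags(subject_row(xy = c(1, 0), date = dates[20]), s2,
                   clinic_xy = c(9, 0), longterm = FALSE)
  expect_equal(r$pm10_lag0, 77)
  expect_equal(unlist(r[paste0("pm10_lag", 1:7)], use.names = FALSE),
               rep(11, 7))
})

test_that("long-term averages use the 182/365-day windows ending at Day -1", {
  dates <- seq(as.Date("2020-01-01"), by = 1, length.out = 400)
  vals <- seq_along(dates)
  s <- make_series(
    data.frame(monitor_id = "M1", x = 0, y = 0),
    data.frame(monitor_id = "M1", date = dates, pm10 = vals,
               temperature = 15, rh = 60, stringsAsFactors = FALSE))
  d0 <- 380L
  r <- assign_lags(subject_row(date = dates[d0]), s, c(0, 0))
  expect_equal(r$pm10_1yr, mean(vals[(d0 - 365):(d0 - 1)]))
  expect_equal(r$pm10_6mo, mean(vals[(d0 - 182):(d0 - 1)]))
  expect_equal(r$app_temp_lag1, apparent_temperature(15, 60))
})

test_that("missing exposure days fail loudly, naming subject and date", {
  dates <- seq(as.Date("2020-01-01"), by = 1, length.out = 40)
  s <- flat_series(list(M1 = 50), dates)
  s$daily$pm10[s$daily$date == dates[18]] <- NA
  expect_error(
    assign_lags(subject_row(id = "S9", date = dates[20]), s, c(0, 0),
                longterm = FALSE),
    "S9.*2020-01-18")
})

test_that("assignment is pure and never reads future data", {
  dates <- seq(as.Date("2020-01-01"), by = 1, length.out = 40)
  set.seed(11)
  vals <- runif(40, 10, 90)
  mk <- function(v) make_series(
    data.frame(monitor_id = "M1", x = 0, y = 0),
    data.frame(monitor_id = "M1", date = dates, pm10 = v,
               temperature = 15, rh = 60, stringsAsFactors = FALSE))
  r1 <- assign_lags(subject_row(date = dates[20]), mk(vals), c(0, 0),
                    longterm = FALSE)
  vals2 <- vals
  vals2[21:40] <- 9999 # future days altered
  r2 <- assign_lags(subject_row(date = dates[20]), mk(vals2), c(0, 0),
                    longterm = FALSE)
  expect_identical(r1, r2)
})
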