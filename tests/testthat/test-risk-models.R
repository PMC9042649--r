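test_that("the shock-risk line reproduces the published anchor points", {
  line <- base_cfg$shock_risk
  expect_equal(shock_probability(line, 0), 0.566)
  expect_equal(shock_probability(line, -3), 0.40)
  expect_equal(shock_probability(line, 3), 0.732)  # 0.566 + 3 * 0.166/3
  # slope of 5.5 percentage points per hour
  expect_equal(shock_probability(line, 1) - shock_probability(line, 0),
               (0.566 - 0.40) / 3)
  # time-independent variant is constant
  line$time_dependent <- FALSE
  expect_equal(shock_probability(line, c(-5, 0, 5)), rep(0.566, 3))
})

test_that("mortality curves reproduce the published values after rounding", {
  m <- base_cfg$mortality
  expect_equal(round(100 * mortality_shock(m, 0), 1), 42.8)
  expect_equal(round(100 * mortality_shock(m, -3), 1), 39.5)
  expect_equal(round(100 * mortality_shock(m, 3), 1), 46.4)
  expect_equal(round(100 * mortality_nonshock(m, 3), 1), 1.6)
  expect_equal(round(100 * mortality_nonshock(m, 1), 1), 0.5)
  expect_equal(mortality_nonshock(m, -3), 0)  # floored at 0 for early treatment
})

test_that("risk functions are monotone in t and clamped to [0,1]", {
  grid <- seq(-50, 200, by = 0.5)
  line <- base_cfg$shock_risk
  m <- base_cfg$mortality
  for (f in list(function(t) shock_probability(line, t),
                 function(t) mortality_shock(m, t),
                 function(t) mortality_nonshock(m, t))) {
    y <- f(grid)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_true(all(mortality_nonshock(m, grid[grid <= 0]) == 0))
})

test_that("alternative mortality models behave as specified", {
  m <- base_cfg$mortality
  m$model <- "kumar"
  expect_equal(mortality_shock(m, 0), 0.40)
  expect_equal(mortality_shock(m, 1) - mortality_shock(m, 0), 0.076)
  m$model <- "lengquist"
  expect_equal(mortality_shock(m, c(-3, 0, 3)), rep(0.33, 3))
  expect_equal(mortality_nonshock(m, c(-3, 0, 3)), rep(0.22, 3))
})

test_that("relative-risk multipliers scale the curves", {
  m <- base_cfg$mortality
  m$rr_shock_multiplier <- 1.5
  m$rr_noshock_multiplier <- 2
  expect_equal(mortality_shock(m, 0), 1.5 * 0.4281)
  expect_equal(mortality_nonshock(m, 2), 2 * 0.0104)
})

test_that("the mortality LP solves forced and exactly-fittable instances", {
  # single interval: the grid value is forced to the empirical fraction
  one <- list(intervals = data.frame(interval_start = -0.5, interval_end = 0.5,
                                     n_patients = 100, n_deaths = 40),
              grid = 0)
  pts <- estimate_mortality_points(one)
  expect_equal(pts$mortality, 0.40, tolerance = 1e-9)
  expect_equal(attr(pts, "objective"), 0, tolerance = 1e-7)

  # monotone empirical fractions: exact fit, objective 0
  iv <- data.frame(interval_start = c(0, 1, 2), interval_end = c(1, 2, 3),
                   n_patients = 1000, n_deaths = c(100, 250, 600))
  pts <- estimate_mortality_points(list(intervals = iv, grid = c(0.5, 1.5, 2.5)))
  expect_equal(pts$mortality, c(0.10, 0.25, 0.60), tolerance = 1e-8)
  expect_equal(attr(pts, "objective"), 0, tolerance = 1e-6)
})

test_that("LP objective is zero exactly when a monotone exact fit exists", {
  # brute-force oracle on one-grid-point-per-interval instances: a monotone
  # exact fit exists iff the empirical fractions are non-decreasing
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- 100
    deaths <- sample(0:n, k, replace = TRUE)
    iv <- data.frame(interval_start = seq_len(k) - 1, interval_end = seq_len(k),
                     n_patients = n, n_deaths = deaths)
    pts <- estimate_mortality_points(list(intervals = iv,
                                          grid = seq_len(k) - 0.5))
    exact_possible <- !is.unsorted(deaths / n)
    if (exact_possible) {
      expect_equal(attr(pts, "objective"), 0, tolerance = 1e-6)
      expect_equal(pts$mortality, deaths / n, tolerance = 1e-7)
    } else {
      expect_gt(attr(pts, "objective"), 1e-6)
    }
    expect_true(all(diff(pts$mortality) >= -1e-9))  # monotone by construction
  }
})

test_that("infeasible grouped data is rejected before the solve", {
  bad <- list(intervals = data.frame(interval_start = 0, interval_end = 1,
                                     n_patients = 10, n_deaths = 11),
              grid = 0.5)
  expect_error(estimate_mortality_points(bad), "deaths")
})

test_that("curve fitting is exact on points drawn from the model family", {
  t <- c(-3, 0, 3)
  pts <- data.frame(t = t, mortality = 0.4281 * exp(0.0272 * t))
  fit <- fit_mortality_curves(pts, "exponential")
  expect_equal(fit$a, 0.4281, tolerance = 1e-9)
  expect_equal(fit$b, 0.0272, tolerance = 1e-9)

  lin <- data.frame(t = 1:3, mortality = 0.0052 * (1:3))
  expect_equal(fit_mortality_curves(lin, "linear_through_origin")$c, 0.0052,
               tolerance = 1e-12)

  # round trip: refitting the fitted curve's own values returns the same fit
  refit <- fit_mortality_curves(
    data.frame(t = t, mortality = fit$a * exp(fit$b * t)), "exponential")
  expect_equal(refit, fit, tolerance = 1e-12)
})

test_that("exponential fit rejects non-positive mortalities naming the point", {
  pts <- data.frame(t = c(-3, 0, 3), mortality = c(0, 0.4, 0.5))
  expect_error(fit_mortality_curves(pts, "exponential"), "-3")
})

test_that("noisy synthetic points recover the generating coefficients", {
  set.seed(202)
  t <- seq(-5, 20, length.out = 50)
  y <- 0.43 * exp(0.027 * t) + rnorm(50, sd = 0.005)
  fit <- fit_mortality_curves(data.frame(t = t, mortality = pmax(y, 1e-4)),
                              "exponential")
  expect_equal(fit$a, 0.43, tolerance = 0.02 / 0.43)
  expect_lt(abs(fit$b - 0.027), 0.005)
})

test_that("grouped mortality CSV round-trips and derives a midpoint grid", {
  iv <- data.frame(interval_start = c(0, 2), interval_end = c(2, 4),
                   n_patients = c(50, 60), n_deaths = c(5, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grouped_mortality(list(intervals = iv), path)
  rd <- read_grouped_mortality(path)
  expect_equal(rd$intervals, iv)
  expect_equal(rd$grid, c(1, 3))
  writeLines("interval_start,foo\n1,2", path)
  expect_error(read_grouped_mortality(path), "missing column")
})
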