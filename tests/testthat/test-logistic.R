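test_that("design rows expand the polynomial basis in the documented order", {
  expect_equal(unname(design_row(0, 0, deg_a = 3)), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(design_row(1, 2, deg_a = 2)), c(1, 2, 4, 1, 2, 4))
  r <- design_row(2009, 79, deg_a = 3, t_offset = 2012)
  expect_equal(unname(r)[1:6], c(1, 79, 6241, 493039, -3, -237))
  expect_error(design_row(1, 1, deg_a = 4), "deg_a")
  expect_error(design_row(1, 1, deg_t = 2), "deg_t")
})

test_that("expit is the logistic function with its exact fixed point", {
  expect_identical(expit(0), 0.5)
  expect_equal(expit(1e3), 1)
  expect_equal(expit(-1e3), 0)
  x <- seq(-5, 5, 0.5)
  expect_true(all(diff(expit(x)) > 0))
  expect_equal(logit(expit(x)), x, tolerance = 1e-12)
})

test_that("a symmetric half/half table fits to the null model", {
  d <- expand.grid(year = c(2009, 2015), age = seq(40, 100, 5))
  d$total <- 1000L; d$cases <- 500L
  fit <- fit_prevalence(d)
  expect_lt(max(abs(fit$alpha)), 1e-6)
  expect_lt(max(abs(fit$beta)), 1e-6)
  expect_equal(expit_eval(fit, 2012, 70), 0.5, tolerance = 1e-8)
})

test_that("fitting exact expected counts recovers the coefficients", {
  tru <- diabetes_like_truth()
  d <- expand.grid(year = c(2009, 2015), age = 40:100)
  d$total <- 1e5
  d$cases <- d$total * expit_eval(tru, d$year, d$age)  # expected counts
  fit <- suppressWarnings(fit_prevalence(d))
  expect_lt(max(abs((fit$alpha - tru$alpha) / tru$alpha)), 1e-8)
  expect_lt(max(abs((fit$beta - tru$beta) / tru$beta)), 1e-8)
  # raw-coordinate evaluation is exact after un-centering
  raw <- coef_raw(fit)
  f_raw <- sum(raw$alpha * 79^(0:3)) + 2009 * sum(raw$beta * 79^(0:3))
  expect_equal(f_raw, predict(fit, 2009, 79, type = "link"), tolerance = 1e-9)
})

test_that("the fitted deviance never exceeds the null deviance", {
  d <- simulate_diabetes_like(totals = 1e4, seed = 5)
  fit <- fit_prevalence(d)
  expect_lt(fit$deviance, fit$null_deviance)
  expect_true(fit$converged)
})

test_that("degenerate designs are rejected with a useful message", {
  d <- expand.grid(year = 2009, age = 40:100)
  d$total <- 100L; d$cases <- 10L
  expect_error(fit_prevalence(d), "2 distinct years")
  d2 <- expand.grid(year = c(2009, 2015), age = c(40, 50, 60))
  d2$total <- 100L; d2$cases <- 10L
  expect_error(fit_prevalence(d2), "distinct ages")
})

test_that("stationary ages solve the quadratic exactly", {
  # df/da = -3 (a - 70)(a - 100): alpha1 = -21000*... build via coefficients
  # f = -a^3 + 255 a^2 - 21000 a  gives f' = -3a^2 + 510 a - 21000
  #   = -3 (a - 70)(a - 100)
  m <- peakdrift:::new_prevalence_fit(
    alpha = c(0, -21000, 255, -1), beta = c(0, 0, 0, 0),
    t_offset = 2000, deg_a = 3, method = "synthetic_truth")
  expect_equal(trace_roots(m, 2005), c(70, 100), tolerance = 1e-12)
  # curvature picks the maximum (f'' = -6a + 510 < 0 at a = 100)
  expect_equal(trace_select(trace_roots(m, 2005), m, 2005), 100)
  # deg_a = 2 single root: f = 10 - (a - 80)^2 / 50
  m2 <- ridge_fit(a0 = 80, drift = 0, w = 50, c = 10)
  expect_equal(trace_roots(m2, 2001), 80, tolerance = 1e-12)
})

test_that("root selection discards implausible and minimum solutions", {
  m <- peakdrift:::new_prevalence_fit(
    alpha = c(0, -21000, 255, -1), beta = c(0, 0, 0, 0),
    t_offset = 2000, deg_a = 3, method = "synthetic_truth")
  expect_equal(trace_select(c(-15, 78.4), diabetes_like_truth(), 2009), 78.4)
  expect_true(is.na(trace_select(c(70), m, 2005)))      # 70 is the minimum
  expect_true(is.na(trace_select(numeric(0), m, 2005)))
  # vanishing cubic coefficient degrades to the quadratic/linear root
  m3 <- peakdrift:::new_prevalence_fit(
    alpha = c(0, 160, -1, 0), beta = c(0, 0, 0, 0),
    t_offset = 2000, deg_a = 3, method = "synthetic_truth")
  expect_warning(r <- trace_roots(m3, 2000), "linear root")
  expect_equal(r, 80)
})

test_that("trace inversion solves a_hat(t) = a0 for the linear ridge", {
  m <- ridge_fit(a0 = 70, t0 = 2000, drift = 0.5, w = 50, c = logit(0.2))
  expect_equal(trace_inverse(m, 80, c(1950, 2100)), 2020, tolerance = 1e-6)
  expect_error(trace_inverse(m, 200, c(1950, 2100)), "not attained")
})

test_that("parametric bootstrap is reproducible and scales like 1/sqrt(n)", {
  d_small <- simulate_diabetes_like(totals = 1e3, seed = 9)
  d_big <- simulate_diabetes_like(totals = 1e5, seed = 9)
  a_r <- seq(50, 95, 5)
  b1 <- bootstrap_prevalence(d_small, B = 200, seed = 123, a_raster = a_r)
  b2 <- bootstrap_prevalence(d_small, B = 200, seed = 123, a_raster = a_r)
  expect_identical(b1, b2)                      # same seed: bit-identical
  b3 <- bootstrap_prevalence(d_big, B = 200, seed = 123, a_raster = a_r)
  w_small <- stats::median(b1$prevalence$high - b1$prevalence$low)
  w_big <- stats::median(b3$prevalence$high - b3$prevalence$low)
  expect_gt(w_small / w_big, 10 * 0.7)          # totals x100 => width / ~10
  expect_lt(w_small / w_big, 10 * 1.3)
  # trace intervals bracket the point trace
  tb <- b3$trace
  expect_true(all(tb$ci_low <= tb$a_hat & tb$a_hat <= tb$ci_high))
})

test_that("prevalence-only input is fit by least squares with CIs disabled", {
  tru <- diabetes_like_truth()
  d <- expand.grid(year = c(2009, 2015), age = 40:100)
  d$prev <- expit_eval(tru, d$year, d$age)
  fit <- fit_prevalence(d, method = "wls")
  expect_lt(max(abs((fit$alpha - tru$alpha) / tru$alpha)), 1e-8)
  expect_null(fit$vcov)
  expect_error(fit_prevalence(d), "required here")
})
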