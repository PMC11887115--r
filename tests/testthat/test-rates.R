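test_that("closed-form perturbation of the polynomial model", {
  # no time interactions and no curvature: zero perturbation
  m0 <- peakdrift:::new_prevalence_fit(
    alpha = c(1, 0.5, 0, 0), beta = c(0.1, 0, 0, 0),
    t_offset = 2000, deg_a = 3, method = "synthetic_truth")
  expect_equal(perturbation_logistic(m0, 2010, 60), 0)
  # pure cubic term: d/da (d/dt + d/da) f = 6 a alpha3
  m1 <- peakdrift:::new_prevalence_fit(
    alpha = c(0, 0, 0, 1), beta = c(0, 0, 0, 0),
    t_offset = 2000, deg_a = 3, method = "synthetic_truth")
  expect_equal(perturbation_logistic(m1, 2005, 7), 42)
  # general coefficients against the written-out formula
  tru <- diabetes_like_truth()
  a <- 79; t <- 2011; tc <- t - tru$t_offset
  al <- tru$alpha; be <- tru$beta
  manual <- be[2] + 2 * a * be[3] + 3 * a^2 * be[4] +
    2 * (al[3] + be[3] * tc) + 6 * a * (al[4] + be[4] * tc)
  expect_equal(perturbation_logistic(tru, t, a), manual, tolerance = 1e-12)
})

test_that("numerical perturbation matches analytic surfaces", {
  # small-p quadratic ridge, time-invariant: p = c - k (a - a0)^2
  tt <- seq(2000, 2010, 0.5); aa <- seq(40, 100, 0.5)
  k <- 2e-5; c0 <- 0.05; a0 <- 70
  vals <- outer(tt, aa, function(t, a) c0 - k * (a - a0)^2)
  s <- prevalence_surface(lexis_grid(tt, aa), vals)
  tt_in <- tt[3:(length(tt) - 2)]              # interior stencil margin
  tr <- trace_curve(tt_in, rep(a0, length(tt_in)), source = "grid_extraction")
  pert <- perturbation_pde(s, tr)
  expect_equal(pert, rep(-2 * k / (1 - c0), length(tt_in)), tolerance = 1e-6)
  # constant-in-t, linear-in-a surface: zero second derivatives
  vals2 <- outer(tt, aa, function(t, a) 0.1 + 0.002 * a)
  s2 <- prevalence_surface(lexis_grid(tt, aa), vals2)
  pert2 <- perturbation_pde(s2, trace_curve(tt_in, rep(70, length(tt_in)),
                                            source = "grid_extraction"))
  expect_lt(max(abs(pert2)), 1e-10)
})

test_that("numerical perturbation converges under grid refinement", {
  tru <- diabetes_like_truth()
  s_of <- function(h) surface_from_model(
    tru, lexis_grid(seq(2007, 2017, h), seq(60, 95, h)))
  tt <- seq(2009, 2015, 1)
  tr <- model_trace(tru, tt)
  class(tr) <- c("trace_curve", "data.frame")
  p1 <- perturbation_pde(s_of(0.5), tr)
  p2 <- perturbation_pde(s_of(0.125), tr)     # 4x refined oracle grid
  expect_lt(max(abs(p1 - p2) / abs(p2)), 0.05)
  # and the refined numerical value matches the closed form: for an expit
  # surface the transport-form perturbation equals p times the polynomial form
  exact <- expit_eval(tru, tt, tr$a_hat) * perturbation_logistic(tru, tt, tr$a_hat)
  expect_lt(max(abs(p2 - exact) / abs(exact)), 0.02)
})

test_that("on-trace incidence slope decomposes exactly on analytic scenarios", {
  tru <- diabetes_like_truth()
  dm_slope <- 0.01
  dm <- function(t, a) 0.05 + dm_slope * (a - 70)
  rates <- incidence_from_model(tru, dm)
  for (t in c(2009, 2012, 2015)) {
    a_hat <- trace_select(trace_roots(tru, t), tru, t)
    got <- incidence_slope_on_trace(tru, t, a_hat, dm_slope = dm_slope)
    # independent high-order numeric derivative of the Lemma-consistent i
    h <- 1e-3
    i_of <- function(a) rate_at(rates, "i", t, a)
    di_num <- (-i_of(a_hat + 2 * h) + 8 * i_of(a_hat + h) -
                 8 * i_of(a_hat - h) + i_of(a_hat - 2 * h)) / (12 * h)
    expect_lt(abs(got$total - di_num), 1e-6)
    expect_equal(got$proportional, got$p * dm_slope)
  }
  # trivial splits of the decomposition, on a symmetric bump centred at 80
  mb <- ridge_fit(a0 = 80, drift = 0, w = 100, c = logit(0.33))
  got <- incidence_slope_on_trace(mb, 2005, 80, dm_slope = 0.01)
  expect_equal(got$perturbation, mb$beta[2] * got$p +
                 got$p * 2 * mb$alpha[3], tolerance = 1e-12)
  expect_equal(got$total - got$perturbation, 0.33 * 0.01, tolerance = 1e-6)
  got0 <- incidence_slope_on_trace(mb, 2005, 80, dm_slope = 0)
  expect_equal(got0$total, got0$perturbation)
  expect_error(incidence_slope_on_trace(mb, 2005, 60, dm_slope = 0.01),
               "off the trace")
})

test_that("proportionality table reports trace year, prevalence and flags", {
  m <- ridge_fit(a0 = 70, t0 = 2000, drift = 0.5, w = 50, c = logit(0.2))
  m$years <- c(2000, 2010)
  tab <- proportionality_table(m, c(70, 75, 80))
  expect_equal(tab$year, c(2000, 2010, 2020), tolerance = 1e-6)
  # on-trace prevalence at the anchor age is the ridge height exactly
  expect_equal(tab$prevalence[1], 0.2, tolerance = 1e-9)
  expect_equal(tab$prevalence,
               expit_eval(m, tab$year, tab$age), tolerance = 1e-9)
  expect_identical(tab$extrapolated, c(FALSE, FALSE, TRUE))
  expect_warning(tab2 <- proportionality_table(m, 200), "never attained")
  expect_true(is.na(tab2$year))
  rep <- proportionality_table(m, 70, report = TRUE)
  expect_equal(rep$year, 2000)
  expect_equal(rep$prevalence, 0.2)
})

test_that("proportionality factor rises with age on the diabetes-like fit", {
  d <- simulate_diabetes_like(totals = 1e5, seed = 20250307)
  fit <- fit_prevalence(d)
  tab <- proportionality_table(fit, c(70, 80, 90, 95), interval = c(1900, 2150))
  expect_true(all(diff(tab$prevalence) > 0))
})
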