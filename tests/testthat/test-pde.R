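test_that("characteristic right-hand side matches the transport equation", {
  rf <- function(i, dm) rate_field(
    i = function(t, a) rep(i, length(t)),
    m0 = function(t, a) rep(0.01, length(t)),
    m1 = function(t, a) rep(0.01 + dm, length(t)))
  # p = 1 is the Riccati fixed point
  expect_equal(characteristic_rhs(5, 1, rf(0.02, 0.01), 2000, 40), 0)
  expect_equal(characteristic_rhs(0, 0, rf(0.02, 0.01), 2000, 40), 0.02)
  expect_equal(characteristic_rhs(0, 0.5, rf(0.02, 0.01), 2000, 40),
               0.5 * (0.02 - 0.005))
})

test_that("constant-rate solutions match the closed form to 1e-8", {
  rf <- rate_field(i = function(t, a) rep(0.01, length(t)))
  sol <- solve_characteristic(rf, 2000, 0, p0 = 0, tau_max = 100, step = 1)
  expect_lt(max(abs(sol$p - (1 - exp(-0.01 * sol$tau)))), 1e-8)
  # non-zero start prevalence
  sol2 <- solve_characteristic(rf, 1990, 20, p0 = 0.3, tau_max = 50, step = 0.5)
  expect_lt(max(abs(sol2$p - (1 - 0.7 * exp(-0.01 * sol2$tau)))), 1e-8)
  expect_equal(tail(sol$p, 1), 1 - exp(-1), tolerance = 1e-8)
})

test_that("degenerate inputs: no inflow stays at zero, p0 = 1 stays at one", {
  rf0 <- rate_field(i = function(t, a) rep(0, length(t)),
                    m0 = function(t, a) rep(0.01, length(t)),
                    m1 = function(t, a) rep(0.05, length(t)))
  sol <- solve_characteristic(rf0, 2000, 0, p0 = 0, tau_max = 80, step = 1)
  expect_true(all(sol$p == 0))
  rf <- make_rate_scenario("age_exponential_incidence")
  sol1 <- solve_characteristic(rf, 2000, 0, p0 = 1, tau_max = 60, step = 1)
  expect_lt(max(abs(sol1$p - 1)), 1e-10)
})

test_that("solver argument validation", {
  rf <- make_rate_scenario("constant")
  expect_error(solve_characteristic(rf, 2000, 0, p0 = 0, tau_max = 10,
                                    step = 0), "step")
  expect_error(solve_characteristic(rf, 2000, 0, p0 = 0, tau_max = -1),
               "tau_max")
  expect_error(solve_characteristic(rf, 2000, 0, p0 = 1.2, tau_max = 1),
               "p0")
})

test_that("adaptive solution matches a dense fixed-step RK4 oracle", {
  # 10 random smooth scenarios: exponential-in-age incidence and Gompertz
  # excess mortality with drifting severity
  set.seed(20240101)
  for (k in 1:10) {
    i0 <- runif(1, 5e-4, 5e-3); ki <- runif(1, 0.02, 0.06)
    d0 <- runif(1, 5e-5, 5e-4); kd <- runif(1, 0.06, 0.11)
    g <- runif(1, -0.01, 0.02)
    rf <- rate_field(
      i = function(t, a) i0 * exp(ki * a) * exp(g * (t - 2000)),
      m0 = function(t, a) rep(0, length(t)),
      m1 = function(t, a) d0 * exp(kd * a))
    sol <- solve_characteristic(rf, 1990, 0, p0 = 0, tau_max = 90, step = 1)
    oracle <- rk4_dense(function(tau, p) characteristic_rhs(tau, p, rf, 1990, 0),
                        p0 = 0, taus = sol$tau, substeps = 100)
    expect_lt(max(abs(sol$p - oracle)), 1e-6)
  }
})

test_that("time-invariant rates give a time-invariant surface", {
  rf <- make_rate_scenario("constant")
  g <- lexis_grid(seq(2000, 2010, 1), seq(0, 100, 2))
  s <- solve_surface(rf, g)
  profile <- 1 - exp(-0.01 * g$a_axis)
  for (j in seq_along(g$t_axis))
    expect_lt(max(abs(s$values[j, ] - profile)), 1e-7)
  # zero incidence: surface identically zero
  rf0 <- rate_field(i = function(t, a) rep(0, length(t)))
  expect_true(all(solve_surface(rf0, g)$values == 0))
})

test_that("surface solver agrees with a first-order upwind oracle and the
          oracle converges at first order", {
  rf <- make_rate_scenario("drifting_incidence")
  g <- lexis_grid(seq(2000, 2010, 0.5), seq(0, 80, 0.5))
  s <- solve_surface(rf, g)
  err <- function(h) {
    up <- upwind_surface(rf, seq(2000, 2010, h), seq(0, 80, h))
    it <- match(round(g$t_axis, 9), round(seq(2000, 2010, h), 9))
    ia <- match(round(g$a_axis, 9), round(seq(0, 80, h), 9))
    max(abs(up[it, ia] - s$values))
  }
  e4 <- err(0.125)   # 4x refined relative to the solver grid
  e8 <- err(0.0625)
  expect_lt(e4, 5e-3)                 # first-order scheme, h = 0.125
  expect_gt(e4 / e8, 1.6)             # halving h about halves the error
  expect_lt(e4 / e8, 2.4)
})

test_that("surface values respect range preservation and boundary checks", {
  rf <- make_rate_scenario("age_exponential_incidence")
  g <- lexis_grid(seq(2000, 2006, 1), seq(0, 110, 1))
  s <- solve_surface(rf, g)
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_error(solve_surface(rf, g, bottom = function(t) rep(1.5, length(t))),
               "outside \\[0, 1\\]")
})
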