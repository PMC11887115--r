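#' Catalogue of parametric rate scenarios
#'
#' Closed, documented set of smooth rate fields for exercising the transport
#' solver and the trace machinery.  Every scenario records its parameters
#' (and closed-form solution where one exists) in the `"meta"` attribute so
#' tests never re-derive the ground truth ad hoc.
#'
#' Scenarios:
#' \describe{
#'   \item{`constant`}{`i = 0.01`, `m0 = m1 = 0.01` (so `dm = 0`).  With
#'     `p(t, 0) = 0` the closed-form surface is `p = 1 - exp(-i a)`,
#'     time-invariant.}
#'   \item{`age_exponential_incidence`}{`i(a) = 0.001 exp(0.05 a)`, Gompertz
#'     excess mortality `dm(a) = 1e-4 exp(0.105 a)` (with Gompertz `m0`).
#'     Time-invariant, with a unique interior age peak of prevalence.}
#'   \item{`drifting_incidence`}{Same age shapes, but incidence grows
#'     smoothly over calendar time: `i(t, a) = 0.001 exp(0.05 a) *
#'     exp(0.012 (t - 2000))`, producing a drifting interior peak.}
#'   \item{`gompertz_mortality_gap`}{Constant incidence `i = 0.01`, Gompertz
#'     `m0(a) = 1e-5 exp(0.1 a)` and proportional hazard `m1 = 2 m0` (so
#'     `dm = m0`).}
#' }
#'
#' @param name Scenario name (see above).
#' @return A [rate_field()] with metadata.
#' @export
make_rate_scenario <- function(name = c("constant",
                                        "age_exponential_incidence",
                                        "drifting_incidence",
                                        "gompertz_mortality_gap")) {
  name <- match.arg(name)
  switch(
    name,
    constant = rate_field(
      i = function(t, a) rep(0.01, length(t)),
      m0 = function(t, a) rep(0.01, length(t)),
      m1 = function(t, a) rep(0.01, length(t)),
      meta = list(name = "constant", i = 0.01, dm = 0,
                  closed_form = function(t, a) 1 - exp(-0.01 * a))),
    age_exponential_incidence = rate_field(
      i = function(t, a) 0.001 * exp(0.05 * a),
      m0 = function(t, a) 1e-4 * exp(0.08 * a),
      m1 = function(t, a) 1e-4 * exp(0.08 * a) + 1e-4 * exp(0.105 * a),
      meta = list(name = "age_exponential_incidence",
                  i0 = 0.001, ki = 0.05, dm0 = 1e-4, kdm = 0.105)),
    drifting_incidence = rate_field(
      i = function(t, a) 0.001 * exp(0.05 * a) * exp(0.012 * (t - 2000)),
      m0 = function(t, a) 1e-4 * exp(0.08 * a),
      m1 = function(t, a) 1e-4 * exp(0.08 * a) + 1e-4 * exp(0.105 * a),
      meta = list(name = "drifting_incidence",
                  i0 = 0.001, ki = 0.05, growth = 0.012, t_ref = 2000,
                  dm0 = 1e-4, kdm = 0.105)),
    gompertz_mortality_gap = rate_field(
      i = function(t, a) rep(0.01, length(t)),
      m0 = function(t, a) 1e-5 * exp(0.1 * a),
      m1 = function(t, a) 2e-5 * exp(0.1 * a),
      meta = list(name = "gompertz_mortality_gap",
                  i = 0.01, m0_0 = 1e-5, k = 0.1, hazard_ratio = 2)))
}

#' Simulate aggregated prevalence counts from a known truth
#'
#' Draws `cases ~ Binomial(total, expit(f*(t, a)))` for every cell of the
#' `years x ages` raster — the same aggregated shape as national claims data
#' (one row per calendar year and one-year age class).  A concentration check
#' (`|observed - truth| <= 4 / sqrt(total)` for at least 99\% of cells) is
#' reported via `message()`.
#'
#' @param truth A `prevalence_fit` (e.g. [diabetes_like_truth()]).
#' @param years,ages Raster of calendar years and ages.
#' @param totals Persons at risk per cell (scalar or per-cell vector).
#' @param seed Mandatory integer seed.
#' @return Data frame `year, age, cases, total, prev`.
#' @export
simulate_counts <- function(truth, years, ages, totals, seed) {
  stopifnot(inherits(truth, "prevalence_fit"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(totals < 1)) stop("totals must be >= 1", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(age = ages, year = years)[, c("year", "age")]
  n <- nrow(grid)
  total <- rep_len(totals, n)
  p <- expit_eval(truth, grid$year, grid$age)
  cases <- stats::rbinom(n, total, p)
  out <- data.frame(year = grid$year, age = grid$age,
                    cases = cases, total = total, prev = cases / total)
  frac <- mean(abs(out$prev - p) <= 4 / sqrt(total))
  if (frac < 0.99)
    message(sprintf(
      "binomial concentration check: only %.1f%% of cells within 4/sqrt(n) of truth",
      100 * frac))
  out
}

#' Synthetic diabetes-like ground truth
#'
#' A fixed expit-polynomial coefficient vector (cubic in age, linear in
#' time, centered at 2012) shaped to mimic the published summary of male
#' type 2 diabetes prevalence in Germany: peak prevalence about 0.30-0.35
#' near age 78-79, the peak trace passing age 79 around 2012.4 with
#' prevalence about 0.33, reaching ages 80/90/95 around calendar years
#' 2017/2067/2090 with prevalences about 0.37/0.83/0.94, and a perturbation
#' term of magnitude below 1e-2 on the observed trace.  This is a synthetic
#' stand-in for the (unavailable) national claims data and is the canonical
#' end-to-end fixture of the package.
#'
#' @return A `prevalence_fit` with known coefficients (no covariance).
#' @export
diabetes_like_truth <- function() {
  new_prevalence_fit(
    alpha = c(2.6855288334550229, -0.43758593061308942,
              0.0094473928266504935, -5.6383746671432412e-05),
    beta = c(0.1220418783658325, -0.0041991162530770846,
             4.5582656642322132e-05, -8.4651589053137117e-08),
    t_offset = 2012, deg_a = 3, a_scale = 1,
    years = c(2009, 2015), method = "synthetic_truth")
}

#' Simulate the canonical diabetes-like aggregated data set
#'
#' Two calendar years (2009, 2015) and one-year ages 40-100, mirroring the
#' two-timepoint structure of the motivating application; default 1e5
#' persons at risk per cell.
#'
#' @param totals Persons at risk per cell (default 1e5).
#' @param seed Integer seed (default 20250307).
#' @return Data frame `year, age, cases, total, prev`.
#' @export
simulate_diabetes_like <- function(totals = 1e5, seed = 20250307) {
  simulate_counts(diabetes_like_truth(), years = c(2009, 2015),
                  ages = 40:100, totals = totals, seed = seed)
}
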