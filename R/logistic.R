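#' Logistic function
#'
#' `expit(x) = 1 / (1 + exp(-x))`, the inverse of the logit.  Saturates
#' cleanly for large `|x|`; `expit(0)` is exactly 0.5.
#' @param x Numeric vector.
#' @export
expit <- function(x) stats::plogis(x)

#' Logit (inverse of expit)
#' @param p Probabilities in (0, 1).
#' @export
logit <- function(p) stats::qlogis(p)

#' Design row of the logistic-polynomial prevalence model
#'
#' The prevalence model is `p(t, a) = expit(f(t, a))` where `f` is polynomial
#' of degree `deg_a` in age and degree 1 in time with full interactions:
#' `f = sum_j alpha_j a^j + t * sum_j beta_j a^j`.  The feature vector is
#' `(1, a, ..., a^deg_a, t, t a, ..., t a^deg_a)` evaluated after centering
#' `t` by `t_offset` and scaling `a` by `a_scale`.
#'
#' @param t,a Calendar year and age (scalars).
#' @param deg_a Age degree, 2 or 3.
#' @param deg_t Time degree, must be 1.
#' @param t_offset Centering constant subtracted from `t`.
#' @param a_scale Multiplier applied to `a` (e.g. `1/100` for conditioning).
#' @return Named numeric vector of length `2 * (deg_a + 1)`.
#' @export
design_row <- function(t, a, deg_a = 3, deg_t = 1, t_offset = 0, a_scale = 1) {
  if (!deg_a %in% c(2, 3)) stop("deg_a must be 2 or 3", call. = FALSE)
  if (deg_t != 1) stop("deg_t must be 1", call. = FALSE)
  tc <- t - t_offset; ac <- a * a_scale
  apow <- ac^(0:deg_a)
  out <- c(apow, tc * apow)
  names(out) <- c(paste0("a", 0:deg_a), paste0("t_a", 0:deg_a))
  out
}

# internal design matrix for vectors t, a
design_matrix <- function(t, a, deg_a, t_offset, a_scale) {
  tc <- t - t_offset; ac <- a * a_scale
  X <- cbind(1, ac, ac^2, if (deg_a == 3) ac^3)
  X <- cbind(X, tc * X)
  colnames(X) <- c(paste0("a", 0:deg_a), paste0("t_a", 0:deg_a))
  X
}

# construct a prevalence_fit object from coefficients given on the
# centered-t, raw-a basis: f = sum alpha_j a^j + (t - t_offset) sum beta_j a^j
new_prevalence_fit <- function(alpha, beta, t_offset, deg_a = 3,
                               a_scale = 1, vcov = NULL, converged = TRUE,
                               years = NULL, n_cells = NA_integer_,
                               deviance = NA_real_, null_deviance = NA_real_,
                               method = "binomial") {
  stopifnot(length(alpha) == deg_a + 1, length(beta) == deg_a + 1)
  structure(
    list(alpha = unname(alpha), beta = unname(beta), t_offset = t_offset,
         a_scale = a_scale, deg_a = deg_a, deg_t = 1L, vcov = vcov,
         converged = converged, years = years, n_cells = n_cells,
         deviance = deviance, null_deviance = null_deviance, method = method),
    class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat(sprintf("<prevalence_fit> expit polynomial, deg_a = %d, deg_t = 1 (%s)\n",
              x$deg_a, x$method))
  cat(sprintf("  t centered at %g; age coefficients alpha, time-interaction beta:\n",
              x$t_offset))
  print(rbind(alpha = x$alpha, beta = x$beta))
  if (!is.na(x$deviance))
    cat(sprintf("  deviance %.4g on %d cells\n", x$deviance, x$n_cells))
  invisible(x)
}

#' Raw-coordinate coefficients of a fitted prevalence model
#'
#' Undoes the internal centering/scaling exactly:
#' `f = sum_j A_j a^j + t * sum_j B_j a^j` in raw years and ages.
#' @param model A [fit_prevalence()] result.
#' @return List with components `alpha` and `beta` (length `deg_a + 1`).
#' @export
coef_raw <- function(model) {
  stopifnot(inherits(model, "prevalence_fit"))
  list(alpha = model$alpha - model$t_offset * model$beta, beta = model$beta)
}

# polynomial helpers on the centered basis -------------------------------

# coefficients (c_0..c_deg) of f(t, .) as a polynomial in raw age
age_poly_coef <- function(model, t) {
  model$alpha + (t - model$t_offset) * model$beta
}

model_f <- function(model, t, a) {
  n <- max(length(t), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  tc <- t - model$t_offset
  out <- model$alpha[1] + tc * model$beta[1]
  for (j in seq_len(model$deg_a))
    out <- out + (model$alpha[j + 1] + tc * model$beta[j + 1]) * a^j
  out
}

# df/da in raw age units
model_fa <- function(model, t, a) {
  n <- max(length(t), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  tc <- t - model$t_offset
  out <- model$alpha[2] + tc * model$beta[2]
  for (j in 2:model$deg_a)
    out <- out + j * (model$alpha[j + 1] + tc * model$beta[j + 1]) * a^(j - 1)
  out
}

model_faa <- function(model, t, a) {
  n <- max(length(t), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  tc <- t - model$t_offset
  out <- 2 * (model$alpha[3] + tc * model$beta[3])
  if (model$deg_a == 3)
    out <- out + 6 * (model$alpha[4] + tc * model$beta[4]) * a
  out
}

model_ft <- function(model, t, a) {
  b <- model$beta
  out <- rep_len(b[1], max(length(t), length(a)))
  a <- rep_len(a, length(out))
  for (j in seq_len(model$deg_a)) out <- out + b[j + 1] * a^j
  out
}

# d2f/(dt da)
model_fta <- function(model, t, a) {
  b <- model$beta
  out <- rep_len(b[2], max(length(t), length(a)))
  a <- rep_len(a, length(out))
  for (j in 2:model$deg_a) out <- out + j * b[j + 1] * a^(j - 1)
  out
}

#' Evaluate modelled prevalence
#'
#' `expit_eval(model, t, a)` returns `expit(f(t, a))` in `(0, 1)`.
#'
#' @param model A [fit_prevalence()] result (or [diabetes_like_truth()]).
#' @param t,a Calendar year(s) and age(s), recycled to a common length.
#' @export
expit_eval <- function(model, t, a) {
  stopifnot(inherits(model, "prevalence_fit"))
  expit(model_f(model, t, a))
}

#' @param object A `prevalence_fit`.
#' @param t,a Coordinates at which to predict.
#' @param type `"response"` for prevalence, `"link"` for the polynomial `f`.
#' @param ... Unused.
#' @rdname expit_eval
#' @export
predict.prevalence_fit <- function(object, t, a,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  f <- model_f(object, t, a)
  if (type == "link") f else expit(f)
}

#' Fit the logistic-polynomial prevalence model to aggregated counts
#'
#' Maximises the binomial log-likelihood
#' `sum(cases * f - total * log(1 + exp(f)))` over the coefficients of the
#' cubic-in-age, linear-in-time polynomial `f` (logistic regression with
#' canonical link on the polynomial basis).  Internally `t` is centered at
#' the mean of the distinct years and `a` is scaled by 1/100 to keep the
#' cubic interaction columns well conditioned; reported coefficients are
#' transformed back to raw years/ages exactly.
#'
#' @param data Data frame with columns `year`, `age`, `cases`, `total`
#'   (e.g. from [read_aggregated()] or [simulate_counts()]).
#' @param deg_a Age degree (2 or 3; default 3).
#' @param deg_t Time degree (must be 1).
#' @param method `"binomial"` (maximum likelihood on counts, default) or
#'   `"wls"` (least squares on observed prevalence, for prevalence-only input;
#'   disables likelihood-based uncertainty).
#' @return A `prevalence_fit`: coefficients on the centered-`t` raw-age basis
#'   (`alpha`, `beta`), the centering constant, the coefficient covariance
#'   (observed-information inverse, on the internal basis), convergence
#'   status and deviance summaries.
#' @export
fit_prevalence <- function(data, deg_a = 3, deg_t = 1,
                           method = c("binomial", "wls")) {
  method <- match.arg(method)
  if (deg_t != 1) stop("deg_t must be 1", call. = FALSE)
  if (!deg_a %in% c(2, 3)) stop("deg_a must be 2 or 3", call. = FALSE)
  data <- validate_aggregated(data, require_counts = method == "binomial")
  years <- sort(unique(data$year))
  if (length(years) < 2) stop("need at least 2 distinct years", call. = FALSE)
  if (length(unique(data$age)) < deg_a + 2)
    stop("need at least deg_a + 2 distinct ages", call. = FALSE)
  t_offset <- mean(years)
  a_scale <- 1 / 100
  X <- design_matrix(data$year, data$age, deg_a, t_offset, a_scale)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (method == "binomial") {
    fit <- stats::glm.fit(X, cbind(data$cases, data$total - data$cases),
                          family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 100))
    # a near-zero deviance defeats the relative-change stopping rule; such
    # fits are at the optimum for all practical purposes
    if (!fit$converged && fit$deviance < 1e-6) fit$converged <- TRUE
    if (!fit$converged)
      stop(sprintf("binomial fit did not converge after %d iterations (deviance %g); possible separation",
                   fit$iter, fit$deviance), call. = FALSE)
    coefs <- fit$coefficients
    # observed-information inverse on the internal basis
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    dev <- fit$deviance
    mu0 <- sum(data$cases) / sum(data$total)
    null_dev <- 2 * sum(binom_dev_cell(data$cases, data$total, mu0))
  } else {
    if (is.null(data$prev))
      stop("wls fitting needs a prev column (or cases/total)", call. = FALSE)
    prev <- data$prev
    fitw <- stats::lm.fit(X, logit(pmin(pmax(prev, 1e-12), 1 - 1e-12)))
    coefs <- fitw$coefficients
    V <- NULL; dev <- sum(fitw$residuals^2); null_dev <- NA_real_
  }
  # undo the age scaling exactly: alpha_j(raw a) = coef_j * a_scale^j
  sj <- a_scale^(0:deg_a)
  alpha <- coefs[1:(deg_a + 1)] * sj
  beta <- coefs[(deg_a + 2):(2 * deg_a + 2)] * sj
  new_prevalence_fit(alpha, beta, t_offset, deg_a = deg_a, a_scale = a_scale,
                     vcov = V, converged = TRUE, years = years,
                     n_cells = nrow(data), deviance = dev,
                     null_deviance = null_dev, method = method)
}

# binomial deviance contribution of one cell at fitted probability mu
binom_dev_cell <- function(cases, total, mu) {
  yb <- cases / total
  t1 <- ifelse(cases > 0, cases * log(yb / mu), 0)
  t2 <- ifelse(cases < total, (total - cases) * log((1 - yb) / (1 - mu)), 0)
  t1 + t2
}

#' Stationary ages of the fitted age profile
#'
#' Solves `df/da = 0` at calendar year `t`.  For `deg_a = 3` this is the
#' quadratic `(alpha1 + beta1 t) + 2 (alpha2 + beta2 t) a +
#' 3 (alpha3 + beta3 t) a^2 = 0`, solved in the numerically stable form that
#' avoids cancellation; for `deg_a = 2` the single linear root.  If the
#' leading coefficient vanishes at this `t` the equation degrades to the
#' lower-order root (with a warning).  Complex roots give an empty set.
#'
#' @param model A `prevalence_fit`.
#' @param t Calendar year (scalar).
#' @return Numeric vector of real stationary ages (possibly empty), sorted.
#' @export
trace_roots <- function(model, t) {
  stopifnot(inherits(model, "prevalence_fit"))
  cf <- age_poly_coef(model, t)
  C <- cf[2]
  B <- 2 * cf[3]
  A <- if (model$deg_a == 3) 3 * cf[4] else 0
  scale <- max(abs(c(A, B, C)))
  if (scale == 0) return(numeric(0))
  if (abs(A) <= 1e-14 * scale) {
    if (model$deg_a == 3)
      warning(sprintf("leading coefficient ~ 0 at t = %g; linear root only", t),
              call. = FALSE)
    if (abs(B) <= 1e-14 * scale) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  roots <- c(q / A, if (q != 0) C / q else -B / A - q / A)
  sort(unique(roots))
}

#' Select the plausible peak age among stationary candidates
#'
#' Keeps candidates inside the plausible age window with negative second
#' derivative of `f` (maxima, not minima); among several, the one with the
#' largest modelled prevalence wins, with ties broken by closeness to the
#' previous year's peak.  Returns `NA` when no candidate survives.
#'
#' @param roots Candidate ages (from [trace_roots()]).
#' @param model A `prevalence_fit`.
#' @param t Calendar year.
#' @param window Plausible-age window, default `c(0, 120)`.
#' @param prev_age Optional previous peak age for continuity tie-breaks.
#' @return Scalar age or `NA_real_`.
#' @export
trace_select <- function(roots, model, t, window = c(0, 120),
                         prev_age = NULL) {
  if (!length(roots)) return(NA_real_)
  keep <- roots[roots >= window[1] & roots <= window[2]]
  keep <- keep[model_faa(model, t, keep) < 0]
  if (!length(keep)) return(NA_real_)
  if (length(keep) > 1) {
    p <- expit_eval(model, t, keep)
    best <- p >= max(p) - 1e-15
    keep <- keep[best]
    if (length(keep) > 1 && !is.null(prev_age))
      keep <- keep[which.min(abs(keep - prev_age))]
  }
  keep[1]
}

#' Analytic prevalence-peak trace of a fitted model
#'
#' Vectorised [trace_roots()] + [trace_select()]: the closed-form trace
#' `a_hat(t)` of the expit-polynomial surface.
#'
#' @param model A `prevalence_fit`.
#' @param t Calendar years (increasing).
#' @param window Plausible-age window for [trace_select()].
#' @return A [trace_curve()] with source `"polynomial_root"`.
#' @export
model_trace <- function(model, t, window = c(0, 120)) {
  a_hat <- rep(NA_real_, length(t))
  prev <- NULL
  for (k in seq_along(t)) {
    a_hat[k] <- trace_select(trace_roots(model, t[k]), model, t[k],
                             window = window, prev_age = prev)
    if (!is.na(a_hat[k])) prev <- a_hat[k]
  }
  trace_curve(t, a_hat, source = "polynomial_root")
}

#' Calendar year at which the trace attains a given age
#'
#' Solves `a_hat(t) = a0` by bracketed root finding (Brent) to `|dt| <= 1e-6`.
#' The trace must attain `a0` with a sign change inside `interval`; years
#' outside the fitted data range are legitimate (extrapolation) and are
#' flagged by [proportionality_table()].
#'
#' @param model A `prevalence_fit`.
#' @param a0 Target age.
#' @param interval Search interval in calendar years.
#' @return Scalar year `t0` with `a_hat(t0) = a0`.
#' @export
trace_inverse <- function(model, a0, interval = c(1900, 2200)) {
  g <- function(t) {
    a <- trace_select(trace_roots(model, t), model, t)
    if (is.na(a)) NA_real_ else a - a0
  }
  tt <- seq(interval[1], interval[2], length.out = 241)
  gv <- vapply(tt, g, numeric(1))
  ok <- which(!is.na(gv[-1]) & !is.na(gv[-length(gv)]) &
                gv[-1] * gv[-length(gv)] <= 0)
  if (!length(ok))
    stop(sprintf("age %g not attained by trace in [%g, %g]",
                 a0, interval[1], interval[2]), call. = FALSE)
  k <- ok[1]
  stats::uniroot(g, c(tt[k], tt[k + 1]), tol = 1e-8)$root
}

#' Parametric bootstrap bands for prevalence and trace
#'
#' Resamples `cases* ~ Binomial(total, fitted p)` cell-wise, refits the model
#' `B` times, and returns percentile confidence bands for the prevalence on a
#' `(t, a)` raster and pointwise intervals for the peak-age trace.
#' Replicates that fail to converge are dropped (an error is raised if more
#' than 10\% drop).  Results are reproducible for a given `seed`.
#'
#' @param data Aggregated counts (columns `year, age, cases, total`).
#' @param deg_a,deg_t Polynomial degrees, see [fit_prevalence()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (default 20250307).
#' @param t_raster,a_raster Raster on which prevalence bands are evaluated;
#'   default: observed years x observed ages.
#' @param trace_t Years at which pointwise trace intervals are computed
#'   (default `t_raster`).
#' @param level Confidence level (default 0.95).
#' @return List with elements `prevalence` (data frame `t, a, fit, low,
#'   high`), `trace` (a [trace_curve()] with bounds), `B_used`, `B_dropped`.
#' @export
bootstrap_prevalence <- function(data, deg_a = 3, deg_t = 1, B = 1000,
                                 seed = 20250307, t_raster = NULL,
                                 a_raster = NULL, trace_t = NULL,
                                 level = 0.95) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  set.seed(seed)
  fit0 <- fit_prevalence(data, deg_a = deg_a, deg_t = deg_t)
  data <- validate_aggregated(data, require_counts = TRUE)
  if (is.null(t_raster)) t_raster <- sort(unique(data$year))
  if (is.null(a_raster)) a_raster <- sort(unique(data$age))
  if (is.null(trace_t)) trace_t <- t_raster
  raster <- expand.grid(t = t_raster, a = a_raster)
  p_fit <- expit_eval(fit0, data$year, data$age)
  pred <- matrix(NA_real_, nrow = B, ncol = nrow(raster))
  tr <- matrix(NA_real_, nrow = B, ncol = length(trace_t))
  dropped <- 0L
  for (b in seq_len(B)) {
    cases_b <- stats::rbinom(nrow(data), data$total, p_fit)
    db <- data; db$cases <- cases_b; db$prev <- cases_b / db$total
    fb <- tryCatch(fit_prevalence(db, deg_a = deg_a, deg_t = deg_t),
                   error = function(e) NULL)
    if (is.null(fb)) { dropped <- dropped + 1L; next }
    pred[b, ] <- expit_eval(fb, raster$t, raster$a)
    tr[b, ] <- model_trace(fb, trace_t)$a_hat
  }
  if (dropped > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed to converge", dropped, B),
         call. = FALSE)
  if (dropped > 0)
    message(sprintf("dropped %d non-converged bootstrap replicate(s)", dropped))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(pred, 2, stats::quantile, probs = probs, na.rm = TRUE)
  prev_band <- data.frame(
    t = raster$t, a = raster$a,
    fit = expit_eval(fit0, raster$t, raster$a),
    low = qs[1, ], high = qs[2, ])
  tq <- apply(tr, 2, stats::quantile, probs = probs, na.rm = TRUE)
  base_tr <- model_trace(fit0, trace_t)$a_hat
  trace_band <- trace_curve(trace_t,
                            a_hat = pmin(pmax(base_tr, tq[1, ]), tq[2, ]),
                            ci_low = tq[1, ], ci_high = tq[2, ],
                            source = "polynomial_root")
  list(prevalence = prev_band, trace = trace_band,
       B_used = B - dropped, B_dropped = dropped, seed = seed, level = level)
}

#' Incidence field consistent with an expit-polynomial surface
#'
#' For any excess-mortality field `dm(t, a)` there is an incidence field that
#' makes the expit-polynomial surface an exact solution of the illness-death
#' transport equation: `i = p * ((d/dt + d/da) f + dm)`.  Returns that field
#' as a [rate_field()] (with `m0 = 0`, `m1 = dm`), suitable for feeding back
#' into [solve_surface()].
#'
#' @param model A `prevalence_fit`.
#' @param dm Vectorised function of `(t, a)` giving excess mortality
#'   (default: zero).
#' @return A [rate_field()].
#' @export
incidence_from_model <- function(model, dm = function(t, a) rep(0, length(t))) {
  stopifnot(inherits(model, "prevalence_fit"))
  force(model); force(dm)
  rate_field(
    i = function(t, a) {
      p <- expit_eval(model, t, a)
      df <- model_ft(model, t, a) + model_fa(model, t, a)
      p * (df + dm(t, a))
    },
    m0 = function(t, a) rep(0, length(t)),
    m1 = function(t, a) dm(t, a),
    meta = list(name = "expit_polynomial_consistent"))
}

#' Materialise an expit-polynomial model on a Lexis grid
#'
#' @param model A `prevalence_fit`.
#' @param grid A [lexis_grid()].
#' @return A [prevalence_surface()] with provenance `"expit_polynomial"`.
#' @export
surface_from_model <- function(model, grid) {
  stopifnot(inherits(model, "prevalence_fit"), inherits(grid, "lexis_grid"))
  vals <- outer(grid$t_axis, grid$a_axis,
                function(t, a) expit_eval(model, t, a))
  prevalence_surface(grid, vals, provenance = "expit_polynomial")
}
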