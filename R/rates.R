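#' Perturbation term on the trace, numerical (surface) form
#'
#' On the peak trace the age slope of incidence decomposes as
#' `di/da = p * d(dm)/da + Pert`, where
#' `Pert(t, a_hat) = 1/(1 - p) * d/da (d/dt + d/da) p` measures the departure
#' from exact proportionality between the age slopes of incidence and excess
#' mortality.  This evaluates `Pert` from a gridded surface by central
#' differences of the mixed and second derivatives.
#'
#' @param surface A [prevalence_surface()].
#' @param trace A [trace_curve()] on (a subset of) the surface years.
#' @return Numeric vector of `Pert(t, a_hat)` per trace row (NA where the
#'   trace is missing).
#' @export
perturbation_pde <- function(surface, trace) {
  stopifnot(inherits(surface, "prevalence_surface"),
            inherits(trace, "trace_curve"))
  derivs <- surface_derivs(surface)
  vapply(seq_len(nrow(trace)), function(k) {
    if (is.na(trace$a_hat[k])) return(NA_real_)
    t <- trace$t[k]; a <- trace$a_hat[k]
    p <- surface_at(surface, t, a)
    if (p >= 1 - 1e-6)
      stop(sprintf("prevalence too close to 1 at (t = %g, a = %g)", t, a),
           call. = FALSE)
    pta <- interp_field(surface, derivs$Ft, t, a)
    paa <- interp_field(surface, derivs$Fa, t, a)
    (pta + paa) / (1 - p)
  }, numeric(1))
}

#' Perturbation term, closed form for the logistic-polynomial model
#'
#' For `p = expit(f)` the perturbation reduces to
#' `Pert = d/da (d/dt + d/da) f`, i.e. for the cubic-in-age, linear-in-time
#' polynomial: `beta1 + 2 a beta2 + 3 a^2 beta3 + 2 (alpha2 + beta2 t) +
#' 6 a (alpha3 + beta3 t)` (raw coordinates).  No numerics involved.
#'
#' @param model A `prevalence_fit`.
#' @param t,a Evaluation point(s), recycled.
#' @return `Pert(t, a)` (units 1/year^2).
#' @export
perturbation_logistic <- function(model, t, a) {
  stopifnot(inherits(model, "prevalence_fit"))
  model_fta(model, t, a) + model_faa(model, t, a)
}

#' Age slope of incidence on the trace
#'
#' Evaluates the on-trace decomposition `di/da = p * d(dm)/da + perturbation`
#' and its proportional approximation `di/da ~ p * d(dm)/da`.  The excess
#' mortality enters only through its age slope `dm_slope`, which may be given
#' symbolically as a number.  For a fitted expit-polynomial model the
#' perturbation contribution is `p * Pert_f` (closed form); for a gridded
#' surface it is the numerical `Pert` of [perturbation_pde()].
#'
#' @param x A `prevalence_fit` or a [prevalence_surface()].
#' @param t Calendar year on the trace.
#' @param a Age on the trace.  For a model, defaults to the trace age at `t`.
#' @param dm_slope Scalar `d(dm)/da` at `(t, a)`.
#' @param trace For the surface method: a [trace_curve()] containing year `t`.
#' @param on_trace_tol Maximum `|dp/da|` (per year of age) accepted as "on
#'   the trace".
#' @return List with elements `total` (full right-hand side), `proportional`
#'   (`p * dm_slope`), `perturbation`, and `p`.
#' @export
incidence_slope_on_trace <- function(x, t, a = NULL, dm_slope, trace = NULL,
                                     on_trace_tol = 1e-6) {
  if (!is.finite(dm_slope)) stop("dm_slope must be finite", call. = FALSE)
  if (inherits(x, "prevalence_fit")) {
    if (is.null(a)) a <- trace_select(trace_roots(x, t), x, t)
    p <- expit_eval(x, t, a)
    dpda <- p * (1 - p) * model_fa(x, t, a)
    if (abs(dpda) > on_trace_tol)
      stop(sprintf("point (t = %g, a = %g) is off the trace: |dp/da| = %g",
                   t, a, abs(dpda)), call. = FALSE)
    pert <- p * perturbation_logistic(x, t, a)
  } else if (inherits(x, "prevalence_surface")) {
    if (is.null(trace))
      stop("the surface method needs a trace curve", call. = FALSE)
    k <- which.min(abs(trace$t - t))
    if (is.null(a)) a <- trace$a_hat[k]
    p <- surface_at(x, t, a)
    derivs <- surface_derivs(x)
    dpda <- interp_field(x, derivs$F, t, a)
    if (abs(dpda) > max(on_trace_tol, 1e-3 * max(abs(derivs$F), na.rm = TRUE)))
      stop(sprintf("point (t = %g, a = %g) is off the trace: |dp/da| = %g",
                   t, a, abs(dpda)), call. = FALSE)
    row <- trace[k, , drop = FALSE]
    row$t <- t; row$a_hat <- a
    class(row) <- class(trace)
    pert <- perturbation_pde(x, row)
  } else stop("x must be a prevalence_fit or prevalence_surface", call. = FALSE)
  list(total = p * dm_slope + pert, proportional = p * dm_slope,
       perturbation = pert, p = p)
}

#' Proportionality table along the (possibly extrapolated) trace
#'
#' For each requested age `a_i`, finds the calendar year `t_i` at which the
#' trace attains `a_i` and the modelled prevalence `p(t_i, a_i)` — the
#' proportionality factor between the age slope of incidence and the age
#' slope of excess mortality at that point.  Years outside the observed data
#' range are flagged as extrapolated.
#'
#' @param model A `prevalence_fit`.
#' @param ages Ages at which to tabulate.
#' @param interval Search interval for [trace_inverse()].
#' @param report If `TRUE`, round years to integers and prevalence to 2
#'   decimals (presentation view); full precision otherwise.
#' @return Data frame with columns `age`, `year`, `prevalence`,
#'   `extrapolated`.  Ages never attained give `NA` year plus a warning.
#' @export
proportionality_table <- function(model, ages, interval = c(1900, 2200),
                                  report = FALSE) {
  stopifnot(inherits(model, "prevalence_fit"))
  years <- model$years
  rows <- lapply(ages, function(a0) {
    t0 <- tryCatch(trace_inverse(model, a0, interval), error = function(e) {
      warning(sprintf("age %g never attained by trace: %s", a0,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    p0 <- if (is.na(t0)) NA_real_ else expit_eval(model, t0, a0)
    extra <- if (is.na(t0) || is.null(years)) NA else
      (t0 < min(years) - 1e-9 | t0 > max(years) + 1e-9)
    data.frame(age = a0, year = t0, prevalence = p0, extrapolated = extra)
  })
  out <- do.call(rbind, rows)
  if (report) {
    out$year <- round(out$year)
    out$prevalence <- round(out$prevalence, 2)
  }
  out
}
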