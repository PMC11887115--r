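#' Trace curve container
#'
#' A data frame of the prevalence-peak trace: per calendar year `t`, the age
#' `a_hat` at which the age profile of prevalence attains its interior
#' maximum, with optional pointwise confidence bounds.
#'
#' @param t Calendar years (strictly increasing).
#' @param a_hat Peak ages (may contain `NA` where no interior peak exists).
#' @param ci_low,ci_high Optional pointwise bounds (`ci_low <= a_hat <=
#'   ci_high` wherever all are present).
#' @param source One of `"grid_extraction"`, `"implicit_ode"`,
#'   `"polynomial_root"`.
#' @return A data frame of class `trace_curve`.
#' @export
trace_curve <- function(t, a_hat, ci_low = NA_real_, ci_high = NA_real_,
                        source = c("grid_extraction", "implicit_ode",
                                   "polynomial_root")) {
  source <- match.arg(source)
  if (any(diff(t) <= 0))
    stop("trace years must be strictly increasing", call. = FALSE)
  ok <- !is.na(a_hat) & !is.na(ci_low) & !is.na(ci_high)
  if (any(ok & (ci_low > a_hat | a_hat > ci_high)))
    stop("trace confidence bounds must bracket a_hat", call. = FALSE)
  out <- data.frame(t = t, a_hat = a_hat,
                    ci_low = rep_len(ci_low, length(t)),
                    ci_high = rep_len(ci_high, length(t)),
                    source = source)
  class(out) <- c("trace_curve", "data.frame")
  out
}

# local interior maxima of a vector; returns integer indices
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# refine a grid argmax by the vertex of the parabola through three nodes
quad_refine <- function(a3, v3) {
  d <- (v3[1] - 2 * v3[2] + v3[3])
  if (d >= 0) return(a3[2])            # not locally concave; keep the node
  h1 <- a3[2] - a3[1]; h2 <- a3[3] - a3[2]
  # general three-point parabola vertex (exact for uniform and non-uniform h)
  num <- v3[1] * (a3[2]^2 - a3[3]^2) + v3[2] * (a3[3]^2 - a3[1]^2) +
    v3[3] * (a3[1]^2 - a3[2]^2)
  den <- 2 * (v3[1] * (a3[2] - a3[3]) + v3[2] * (a3[3] - a3[1]) +
                v3[3] * (a3[1] - a3[2]))
  if (den == 0) return(a3[2])
  num / den
}

#' Extract the prevalence-peak trace from a surface, year by year
#'
#' For each calendar-year knot the age profile `p(t, .)` is scanned for its
#' interior maximum inside `age_window`; the argmax node is refined by
#' quadratic interpolation through the node and its two neighbours.  Years
#' whose maximum sits on the window edge, or whose profile is flat, are
#' recorded as missing (with a warning), never extrapolated.  When several
#' interior maxima exist, the one with the largest prevalence is kept; ties
#' are broken by continuity (closeness to the previous year's peak).
#'
#' @param surface A [prevalence_surface()].
#' @param age_window Numeric `c(a_min, a_max)` restricting the search;
#'   defaults to the full age axis.
#' @return A [trace_curve()] with source `"grid_extraction"`.
#' @export
extract_peak_trace <- function(surface, age_window = NULL) {
  stopifnot(inherits(surface, "prevalence_surface"))
  g <- surface$grid
  if (is.null(age_window)) age_window <- range(g$a_axis)
  sel <- which(g$a_axis >= age_window[1] & g$a_axis <= age_window[2])
  if (length(sel) < 3)
    stop("age_window must contain at least 3 age knots", call. = FALSE)
  a_sub <- g$a_axis[sel]
  a_hat <- rep(NA_real_, length(g$t_axis))
  n_missing <- 0L
  prev <- NA_real_
  for (j in seq_along(g$t_axis)) {
    v <- surface$values[j, sel]
    if (max(v) - min(v) <= .Machine$double.eps * 10) { n_missing <- n_missing + 1L; next }
    cand <- local_maxima(v)
    if (!length(cand)) { n_missing <- n_missing + 1L; next }
    if (length(cand) > 1) {
      best_p <- max(v[cand])
      cand <- cand[v[cand] >= best_p - 1e-12]
      if (length(cand) > 1 && !is.na(prev))
        cand <- cand[which.min(abs(a_sub[cand] - prev))]
      cand <- cand[1]
    }
    k <- cand
    a_hat[j] <- quad_refine(a_sub[(k - 1):(k + 1)], v[(k - 1):(k + 1)])
    prev <- a_hat[j]
  }
  if (n_missing > 0)
    warning(sprintf("%d year(s) without an interior peak recorded as missing",
                    n_missing), call. = FALSE)
  trace_curve(g$t_axis, a_hat, source = "grid_extraction")
}

# central-difference derivative fields of a surface; rows t, cols a.
# Returns F = dp/da, and its derivatives Ft, Fa, plus p_aa and p_ta.
# Edge rows/cols are NA (second-order interior stencils only).
surface_derivs <- function(surface) {
  p <- surface$values
  ts <- surface$grid$t_axis; as <- surface$grid$a_axis
  nt <- nrow(p); na <- ncol(p)
  dt <- diff(ts); da <- diff(as)
  cd <- function(M, h, along) {
    D <- matrix(NA_real_, nt, na)
    if (along == "a") {
      for (k in 2:(na - 1))
        D[, k] <- (M[, k + 1] - M[, k - 1]) / (as[k + 1] - as[k - 1])
    } else {
      for (k in 2:(nt - 1))
        D[k, ] <- (M[k + 1, ] - M[k - 1, ]) / (ts[k + 1] - ts[k - 1])
    }
    D
  }
  Fm <- cd(p, da, "a")          # dp/da
  Ft <- cd(Fm, dt, "t")         # d2p/dtda
  Fa <- cd(Fm, da, "a")         # d2p/da2 (wide stencil)
  list(F = Fm, Ft = Ft, Fa = Fa)
}

# interpolate a derivative field (with NA margins) at (t, a)
interp_field <- function(surface, M, t, a) {
  g <- surface$grid
  ts <- g$t_axis; as <- g$a_axis
  rt <- range(ts[rowSums(!is.na(M)) > 0])
  ra <- range(as[colSums(!is.na(M)) > 0])
  if (any(t < rt[1] | t > rt[2] | a < ra[1] | a > ra[2]))
    stop(sprintf("(t = %g, a = %g) outside the interior stencil margin",
                 t[1], a[1]), call. = FALSE)
  keep_t <- ts >= rt[1] & ts <= rt[2]
  keep_a <- as >= ra[1] & as <= ra[2]
  pracma::interp2(ts[keep_t], as[keep_a], t(M[keep_t, keep_a, drop = FALSE]),
                  t, a, method = "linear")
}

#' Slope of the trace from the implicit-function-theorem ODE
#'
#' On the trace, `F(t, a) = dp/da` vanishes.  Where `dF/da != 0` the implicit
#' function theorem gives the trace slope `a'(t) = -(dF/dt) / (dF/da)`.  All
#' derivatives are second-order central differences on the surface grid,
#' bilinearly interpolated at `(t, a)`; the point must lie at least two cells
#' inside the grid.
#'
#' @param t,a Query point (scalar).
#' @param surface A [prevalence_surface()].
#' @param derivs Optional precomputed result of the internal derivative
#'   stencils (used by [integrate_trace()] to avoid recomputation).
#' @return Scalar slope `a'(t)` in years of age per calendar year.
#' @export
implicit_trace_rhs <- function(t, a, surface, derivs = NULL) {
  if (is.null(derivs)) derivs <- surface_derivs(surface)
  Ft <- interp_field(surface, derivs$Ft, t, a)
  Fa <- interp_field(surface, derivs$Fa, t, a)
  thresh <- 1e-12 * max(abs(derivs$F), na.rm = TRUE)
  if (!is.finite(Fa) || abs(Fa) <= thresh)
    stop(sprintf("trace existence condition violated at (t = %g, a = %g): |dF/da| = %g",
                 t, a, abs(Fa)), call. = FALSE)
  -Ft / Fa
}

#' Propagate the trace by integrating the implicit ODE
#'
#' Starting from an on-trace point `(t_start, a_start)`, integrates
#' `a'(t) = -(dF/dt)/(dF/da)` (with `F = dp/da`) by classical RK4 with fixed
#' step equal to the time-grid spacing.  If the existence condition
#' `dF/da != 0` fails (or the curve leaves the interior margin) the
#' integration stops early and the returned curve carries attribute
#' `status = "stopped_early"`; otherwise `status = "ok"`.
#'
#' @param surface A [prevalence_surface()].
#' @param t_start Start year (must be a knot of the time axis).
#' @param a_start Start age; must satisfy the on-trace condition
#'   `|dp/da| <= 1e-6 * max(p)` per year of age.  If `NULL`, it is
#'   bootstrapped from [extract_peak_trace()] at `t_start`.
#' @param t_end End year (a knot, `> t_start`).
#' @return A [trace_curve()] with source `"implicit_ode"`.
#' @export
integrate_trace <- function(surface, t_start, a_start = NULL, t_end) {
  stopifnot(inherits(surface, "prevalence_surface"))
  g <- surface$grid
  ts <- g$t_axis
  j0 <- which.min(abs(ts - t_start))
  if (abs(ts[j0] - t_start) > 1e-9)
    stop("t_start must be a knot of the time axis", call. = FALSE)
  j1 <- which.min(abs(ts - t_end))
  if (j1 <= j0) stop("t_end must exceed t_start", call. = FALSE)
  derivs <- surface_derivs(surface)
  if (is.null(a_start)) {
    et <- extract_peak_trace(surface)
    a_start <- et$a_hat[j0]
    if (is.na(a_start))
      stop("no interior peak at t_start to bootstrap the trace from",
           call. = FALSE)
  }
  res <- interp_field(surface, derivs$F, t_start, a_start)
  # base tolerance plus a half-cell allowance scaled by local curvature,
  # since a grid-extracted start carries O(h^2) discretisation error
  curv <- abs(interp_field(surface, derivs$Fa, t_start, a_start))
  da <- max(diff(g$a_axis))
  tol <- max(1e-6 * max(abs(surface$values)), 0.6 * curv * da)
  if (abs(res) > tol)
    stop(sprintf("start point is not on the trace: |dp/da| = %g > %g",
                 abs(res), tol), call. = FALSE)
  a_out <- rep(NA_real_, j1 - j0 + 1)
  a_out[1] <- a_start
  status <- "ok"
  a <- a_start
  for (j in j0:(j1 - 1)) {
    h <- ts[j + 1] - ts[j]
    step <- tryCatch({
      k1 <- implicit_trace_rhs(ts[j], a, surface, derivs)
      k2 <- implicit_trace_rhs(ts[j] + h / 2, a + h * k1 / 2, surface, derivs)
      k3 <- implicit_trace_rhs(ts[j] + h / 2, a + h * k2 / 2, surface, derivs)
      k4 <- implicit_trace_rhs(ts[j] + h, a + h * k3, surface, derivs)
      a + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }, error = function(e) NA_real_)
    if (is.na(step)) { status <- "stopped_early"; break }
    a <- step
    a_out[j - j0 + 2] <- a
  }
  out <- trace_curve(ts[j0:j1], a_out, source = "implicit_ode")
  attr(out, "status") <- status
  out
}

#' Second age-derivative of prevalence along a trace
#'
#' Central-difference check that each trace point is a maximum (negative
#' curvature), not a minimum.
#'
#' @param surface A [prevalence_surface()].
#' @param trace A [trace_curve()].
#' @return Numeric vector `d2p/da2` at `(t, a_hat)` (NA where `a_hat` is NA).
#' @export
trace_curvature <- function(surface, trace) {
  derivs <- surface_derivs(surface)
  vapply(seq_len(nrow(trace)), function(k) {
    if (is.na(trace$a_hat[k])) return(NA_real_)
    interp_field(surface, derivs$Fa, trace$t[k], trace$a_hat[k])
  }, numeric(1))
}
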