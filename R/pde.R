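#' Right-hand side of the prevalence transport equation along a characteristic
#'
#' The prevalence `p(t, a)` of an irreversible chronic disease obeys the
#' transport equation `(d/dt + d/da) p = (1 - p) (i - p dm)` on the Lexis
#' plane.  Along the characteristic line `(t0 + tau, a0 + tau)` the equation
#' becomes a scalar Riccati ODE in `tau`; this function evaluates its
#' right-hand side.  `p == 1` is the special (fixed-point) solution.
#'
#' @param tau Time along the characteristic (years).
#' @param p Prevalence in `[0, 1]`.
#' @param rates A [rate_field()].
#' @param t0,a0 Anchor year and age of the characteristic.
#' @return `dp/dtau = (1 - p) (i - p dm)` at `(t0 + tau, a0 + tau)`.
#' @export
characteristic_rhs <- function(tau, p, rates, t0, a0) {
  t <- t0 + tau; a <- a0 + tau
  i <- rate_at(rates, "i", t, a)
  dm <- rate_at(rates, "dm", t, a)
  (1 - p) * (i - p * dm)
}

#' Integrate prevalence along one characteristic
#'
#' Solves the Riccati ODE `dp/dtau = (1 - p)(i - p dm)` along the line
#' `(t0 + tau, a0 + tau)` with an adaptive 5th-order Runge-Kutta
#' (Dormand-Prince) integrator.  For constant rates with `dm = 0` the exact
#' solution is `1 - (1 - p0) exp(-i tau)`.
#'
#' @param rates A [rate_field()].
#' @param t0,a0 Anchor year and age (`tau = 0`).
#' @param p0 Initial prevalence in `[0, 1]`.
#' @param tau_max Duration of integration (years, `>= 0`).
#' @param step Output sampling step (years, `> 0`); the integrator chooses its
#'   own internal steps.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data frame with columns `tau`, `t`, `a`, `p`; `p` is clipped to
#'   `[0, 1]` on output (excursions never exceed 1e-9 at the default
#'   tolerances).
#' @export
solve_characteristic <- function(rates, t0, a0, p0 = 0, tau_max, step = 0.1,
                                 rtol = 1e-8, atol = 1e-10) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (tau_max < 0) stop("tau_max must be >= 0", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]", call. = FALSE)
  taus <- unique(c(seq(0, tau_max, by = step), tau_max))
  if (tau_max == 0) {
    return(data.frame(tau = 0, t = t0, a = a0, p = p0))
  }
  sol <- deSolve::ode(
    y = c(p = p0), times = taus, parms = NULL,
    func = function(tau, y, parms) {
      list(characteristic_rhs(tau, y[[1]], rates, t0, a0))
    },
    method = "ode45", rtol = rtol, atol = atol)
  p <- sol[, "p"]
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop("characteristic solution left [0, 1] beyond tolerance", call. = FALSE)
  data.frame(tau = sol[, "time"], t = t0 + sol[, "time"],
             a = a0 + sol[, "time"], p = pmin(pmax(p, 0), 1))
}

#' Solve the prevalence surface on a Lexis grid by characteristics
#'
#' Every grid node lies on a characteristic (a 45-degree line of the Lexis
#' plane).  The node value is obtained by integrating the Riccati ODE from the
#' boundary anchor of its characteristic.  By default each characteristic is
#' anchored at age 0 with `p(t, 0) = 0` (no congenital prevalence).  If a
#' `left` boundary is supplied, characteristics are instead anchored at
#' whichever grid edge (bottom age edge or left time edge) the backward
#' characteristic reaches first.
#'
#' @param rates A [rate_field()].
#' @param grid A [lexis_grid()].
#' @param bottom Function of `t` giving prevalence on the bottom age edge of
#'   the anchoring scheme (age 0 when `left` is `NULL`, otherwise
#'   `min(grid$a_axis)`).  Default: 0.
#' @param left Optional function of `a` giving prevalence on the left time
#'   edge `t = min(grid$t_axis)`.  When `NULL` (default), all characteristics
#'   are traced back to age 0, which requires the rate field to be evaluable
#'   at years before `min(grid$t_axis)`.
#' @param rtol,atol Solver tolerances, see [solve_characteristic()].
#' @return A [prevalence_surface()] with provenance `"pde_solution"`.
#' @export
solve_surface <- function(rates, grid, bottom = function(t) rep(0, length(t)),
                          left = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(rates, "rate_field"), inherits(grid, "lexis_grid"))
  ts <- grid$t_axis; as <- grid$a_axis
  a_floor <- if (is.null(left)) 0 else min(as)
  nodes <- expand.grid(ti = seq_along(ts), ai = seq_along(as))
  nodes$t <- ts[nodes$ti]; nodes$a <- as[nodes$ai]
  # characteristic identity: birth cohort b = t - a (shifted to the anchor)
  if (is.null(left)) {
    nodes$delta <- nodes$a - a_floor           # distance back to age floor
  } else {
    nodes$delta <- pmin(nodes$a - a_floor, nodes$t - ts[1])
  }
  nodes$t_anchor <- nodes$t - nodes$delta
  nodes$a_anchor <- nodes$a - nodes$delta
  p0_of <- function(t_anchor, a_anchor) {
    if (!is.null(left) && a_anchor > a_floor + 1e-12) left(a_anchor)
    else bottom(t_anchor)
  }
  vals <- matrix(NA_real_, nrow = length(ts), ncol = length(as))
  # group nodes sharing a characteristic and integrate each line once
  key <- round(nodes$t - nodes$a, 9)
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- nodes[idx, ]
    o <- order(sub$delta)
    sub <- sub[o, ]; idx <- idx[o]
    t_anchor <- sub$t_anchor[1]; a_anchor <- sub$a_anchor[1]
    p0 <- p0_of(t_anchor, a_anchor)
    if (!is.finite(p0) || p0 < 0 || p0 > 1)
      stop(sprintf("boundary value %g at (t = %g, a = %g) outside [0, 1]",
                   p0, t_anchor, a_anchor), call. = FALSE)
    taus <- sub$delta                       # tau = 0 at the anchor
    times <- sort(unique(c(0, taus)))
    if (length(times) == 1) {
      p <- rep(p0, nrow(sub))
    } else {
      sol <- deSolve::ode(
        y = c(p = p0), times = times, parms = NULL,
        func = function(tau, y, parms) {
          list(characteristic_rhs(tau, y[[1]], rates, t_anchor, a_anchor))
        },
        method = "ode45", rtol = rtol, atol = atol)
      p <- sol[match(round(taus, 9), round(sol[, "time"], 9)), "p"]
    }
    vals[cbind(sub$ti, sub$ai)] <- pmin(pmax(p, 0), 1)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("characteristic through node (t = %g, a = %g) has no boundary anchor",
                 ts[bad[1]], as[bad[2]]), call. = FALSE)
  }
  prevalence_surface(grid, vals, provenance = "pde_solution")
}
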