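#' Transition-rate field of the illness-death model
#'
#' Bundles the three transition rates of the irreversible illness-death model
#' as scalar fields on the Lexis plane: the incidence rate `i(t, a)`, the
#' mortality rate of the non-diseased `m0(t, a)` and the mortality rate of the
#' diseased `m1(t, a)` (all per person-year, with `t` calendar year and `a`
#' age in years).  The excess mortality `dm = m1 - m0` is always derived from
#' `m0` and `m1`, never stored separately, so the identity `dm == m1 - m0`
#' holds exactly.
#'
#' @param i,m0,m1 Vectorised functions of `(t, a)` returning non-negative
#'   rates per person-year.
#' @param meta Optional list of metadata (e.g. closed-form expressions for
#'   generated scenarios); stored as attribute `"meta"`.
#'
#' @return An object of class `rate_field` with elements `i`, `m0`, `m1` and
#'   the derived `dm`.
#' @examples
#' rf <- rate_field(
#'   i  = function(t, a) 0.001 * exp(0.05 * a),
#'   m0 = function(t, a) 1e-4 * exp(0.09 * a),
#'   m1 = function(t, a) 2e-4 * exp(0.09 * a)
#' )
#' rate_at(rf, "dm", 2000, 70)
#' @export
rate_field <- function(i, m0 = function(t, a) rep(0, length(t)),
                       m1 = m0, meta = NULL) {
  stopifnot(is.function(i), is.function(m0), is.function(m1))
  out <- structure(
    list(i = i, m0 = m0, m1 = m1,
         dm = function(t, a) m1(t, a) - m0(t, a)),
    class = "rate_field")
  attr(out, "meta") <- meta
  out
}

#' Evaluate one field of a rate_field with finiteness checks
#'
#' @param rates A [rate_field()].
#' @param field One of `"i"`, `"m0"`, `"m1"`, `"dm"`.
#' @param t,a Coordinates (recycled to common length).
#' @return Numeric vector of rates.  Non-finite values raise an error naming
#'   the offending field and the first offending coordinate.
#' @export
rate_at <- function(rates, field = c("i", "m0", "m1", "dm"), t, a) {
  stopifnot(inherits(rates, "rate_field"))
  field <- match.arg(field)
  n <- max(length(t), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  v <- rates[[field]](t, a)
  if (anyNA(v) || any(!is.finite(v))) {
    k <- which(!is.finite(v))[1]
    stop(sprintf("non-finite rate '%s' at (t = %g, a = %g)", field, t[k], a[k]),
         call. = FALSE)
  }
  if (field != "dm" && any(v < 0)) {
    k <- which(v < 0)[1]
    stop(sprintf("negative rate '%s' at (t = %g, a = %g)", field, t[k], a[k]),
         call. = FALSE)
  }
  v
}

#' @export
print.rate_field <- function(x, ...) {
  cat("<rate_field>")
  meta <- attr(x, "meta")
  if (!is.null(meta$name)) cat(" scenario:", meta$name)
  cat("\n  fields: i, m0, m1, dm = m1 - m0\n")
  invisible(x)
}

#' Build a rate field from a gridded long-format table
#'
#' Reads a table with columns `t, a, i, m0, m1` (one row per grid node of a
#' complete rectangular grid) and returns a [rate_field()] whose fields
#' bilinearly interpolate the table.  Queries outside the tabulated rectangle
#' are clamped to the nearest edge; the first such query raises a warning.
#'
#' @param x A data frame with columns `t, a, i, m0, m1`, or a path to a CSV
#'   file with that header.
#' @return A [rate_field()].
#' @export
rate_field_from_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x)
  need <- c("t", "a", "i", "m0", "m1")
  if (!all(need %in% names(x)))
    stop("rate table must have columns: ", paste(need, collapse = ", "),
         "; found: ", paste(names(x), collapse = ", "), call. = FALSE)
  ts <- sort(unique(x$t)); as <- sort(unique(x$a))
  if (nrow(x) != length(ts) * length(as))
    stop("rate table is not a complete t x a grid", call. = FALSE)
  ord <- order(x$a, x$t)   # interp2: rows = y (a), cols = x (t)
  make_interp <- function(col) {
    Z <- matrix(x[[col]][ord], nrow = length(as), ncol = length(ts),
                byrow = TRUE)
    warned <- FALSE
    function(t, a) {
      n <- max(length(t), length(a))
      t <- rep_len(t, n); a <- rep_len(a, n)
      out_of_range <- t < ts[1] | t > ts[length(ts)] |
        a < as[1] | a > as[length(as)]
      if (any(out_of_range) && !warned) {
        warned <<- TRUE
        warning(sprintf(
          "rate query outside table (first at t = %g, a = %g); clamped to edge",
          t[which(out_of_range)[1]], a[which(out_of_range)[1]]), call. = FALSE)
      }
      tc <- pmin(pmax(t, ts[1]), ts[length(ts)])
      ac <- pmin(pmax(a, as[1]), as[length(as)])
      pracma::interp2(ts, as, Z, tc, ac, method = "linear")
    }
  }
  rate_field(i = make_interp("i"), m0 = make_interp("m0"),
             m1 = make_interp("m1"),
             meta = list(name = "gridded_table",
                         t_range = range(ts), a_range = range(as)))
}

#' Discretisation of the Lexis plane
#'
#' @param t_axis Strictly increasing calendar-year knots (at least 2).
#' @param a_axis Strictly increasing age knots (at least 2) within `[0, 120]`.
#' @return A `lexis_grid` with axes and uniform-spacing flags.
#' @export
lexis_grid <- function(t_axis, a_axis) {
  t_axis <- as.numeric(t_axis); a_axis <- as.numeric(a_axis)
  if (length(t_axis) < 2 || length(a_axis) < 2)
    stop("lexis_grid needs at least 2 knots per axis", call. = FALSE)
  if (any(diff(t_axis) <= 0) || any(diff(a_axis) <= 0))
    stop("lexis_grid axes must be strictly increasing", call. = FALSE)
  if (min(a_axis) < 0 || max(a_axis) > 120)
    stop("age axis must lie within [0, 120]", call. = FALSE)
  near_uniform <- function(x) {
    d <- diff(x)
    abs(max(d) - min(d)) <= 1e-9 * max(abs(d))
  }
  structure(
    list(t_axis = t_axis, a_axis = a_axis,
         t_uniform = near_uniform(t_axis), a_uniform = near_uniform(a_axis)),
    class = "lexis_grid")
}

#' @export
print.lexis_grid <- function(x, ...) {
  cat(sprintf("<lexis_grid> t: %g..%g (%d knots), a: %g..%g (%d knots)\n",
              min(x$t_axis), max(x$t_axis), length(x$t_axis),
              min(x$a_axis), max(x$a_axis), length(x$a_axis)))
  invisible(x)
}

#' Gridded prevalence on a Lexis rectangle
#'
#' @param grid A [lexis_grid()].
#' @param values Matrix of prevalence values, rows indexed by `grid$t_axis`
#'   and columns by `grid$a_axis`; all values finite and in `[0, 1]`.
#' @param provenance One of `"pde_solution"`, `"expit_polynomial"`,
#'   `"external"`.
#' @return A `prevalence_surface`.
#' @export
prevalence_surface <- function(grid, values,
                               provenance = c("external", "pde_solution",
                                              "expit_polynomial")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(grid, "lexis_grid"), is.matrix(values))
  if (nrow(values) != length(grid$t_axis) ||
      ncol(values) != length(grid$a_axis))
    stop("values must be length(t_axis) x length(a_axis)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("prevalence surface contains non-finite values", call. = FALSE)
  if (min(values) < 0 || max(values) > 1)
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "prevalence_surface")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf("<prevalence_surface> [%s] %d x %d, p in [%.4g, %.4g]\n",
              x$provenance, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.prevalence_surface <- function(x, ...) {
  data.frame(
    t = rep(x$grid$t_axis, times = length(x$grid$a_axis)),
    a = rep(x$grid$a_axis, each = length(x$grid$t_axis)),
    p = as.vector(x$values))
}

# bilinear interpolation of the surface at arbitrary (t, a); internal
surface_at <- function(surface, t, a) {
  g <- surface$grid
  pracma::interp2(g$t_axis, g$a_axis, t(surface$values), t, a,
                  method = "linear")
}

#' Build a rate field from a YAML configuration of parametric families
#'
#' The YAML file defines one block per field (`i`, `m0`, `m1`), each with a
#' `family` and its parameters:
#' \describe{
#'   \item{`constant`}{`value`}
#'   \item{`exponential_age`}{`rate(a) = c * exp(k * a)`: needs `c`, `k`}
#'   \item{`logistic_age`}{`rate(a) = max / (1 + exp(-k (a - midpoint)))`:
#'     needs `max`, `k`, `midpoint`}
#' }
#' Omitted `m0`/`m1` blocks default to zero.
#'
#' @param path Path to the YAML file.
#' @return A [rate_field()].
#' @export
rate_field_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(block) {
    if (is.null(block)) return(function(t, a) rep(0, length(t)))
    switch(
      block$family,
      constant = {
        v <- block$value
        function(t, a) rep(v, length(t))
      },
      exponential_age = {
        cc <- block$c; k <- block$k
        function(t, a) cc * exp(k * a)
      },
      logistic_age = {
        mx <- block$max; k <- block$k; mid <- block$midpoint
        function(t, a) mx / (1 + exp(-k * (a - mid)))
      },
      stop("unknown rate family: ", block$family, call. = FALSE))
  }
  rate_field(i = build(cfg$i), m0 = build(cfg$m0), m1 = build(cfg$m1),
             meta = list(name = "yaml_config", config = cfg))
}
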