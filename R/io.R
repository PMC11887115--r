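# readers/writers for the package's tabular dialects and model JSON

# column aliases accepted by read_aggregated (first match wins)
.aggregated_aliases <- list(
  year = c("year", "t", "yr", "calendar_year"),
  age = c("age", "a"),
  cases = c("cases", "n_disease", "ndisease", "diseased", "n_cases"),
  total = c("total", "n_total", "ntotal", "n", "at_risk"),
  prev = c("prev", "prevalence", "p"),
  sex = c("sex", "gender"))

# internal: enforce AggregatedPrevalence invariants, report offending lines
validate_aggregated <- function(data, require_counts = TRUE) {
  need <- c("year", "age")
  if (!all(need %in% names(data)))
    stop("aggregated data must have columns year, age (+ cases, total)",
         call. = FALSE)
  has_counts <- all(c("cases", "total") %in% names(data))
  if (require_counts && !has_counts)
    stop("count columns cases/total are required here (prevalence-only input ",
         "supports only the weighted least-squares path)", call. = FALSE)
  if (has_counts) {
    bad <- which(data$total < 1)
    if (length(bad))
      stop("total < 1 on data line ", bad[1] + 1L, call. = FALSE)
    bad <- which(data$cases < 0 | data$cases > data$total)
    if (length(bad))
      stop("cases outside [0, total] on data line ", bad[1] + 1L, call. = FALSE)
    data$prev <- data$cases / data$total
  }
  if (anyDuplicated(data[, c("year", "age")]))
    stop("duplicate (year, age) pairs in aggregated data", call. = FALSE)
  data
}

#' Read an aggregated prevalence table
#'
#' Reads a whitespace-, tab- or comma-delimited table with a header and maps
#' common column aliases (`t` for `year`, `a` for `age`, `n_disease` for
#' `cases`, `n_total` for `total`).  An optional `sex` column is used as a
#' filter.  Tables carrying only a prevalence column (no counts) are parsed
#' in prevalence-only mode, flagged via `attr(x, "ci_disabled")`; such data
#' support only the least-squares fitting path.
#'
#' @param path File path.
#' @param sex Optional value to filter the `sex` column on (e.g. `"male"`).
#' @return Validated data frame with columns `year, age, cases, total, prev`
#'   (counts absent in prevalence-only mode).
#' @export
read_aggregated <- function(path, sex = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  out <- list()
  for (canon in names(.aggregated_aliases)) {
    hit <- which(nm %in% .aggregated_aliases[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  if (!all(c("year", "age") %in% names(out)))
    stop("missing required columns after alias mapping; expected year/t and ",
         "age/a, found: ", paste(names(raw), collapse = ", "), call. = FALSE)
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!is.null(sex)) {
    if (is.null(df$sex))
      stop("sex filter requested but no sex column found", call. = FALSE)
    df <- df[tolower(df$sex) == tolower(sex) |
               substr(tolower(df$sex), 1, 1) == substr(tolower(sex), 1, 1), ]
  }
  df$sex <- NULL
  has_counts <- all(c("cases", "total") %in% names(df))
  if (!has_counts && is.null(df$prev))
    stop("need either cases/total counts or a prevalence column", call. = FALSE)
  df <- validate_aggregated(df, require_counts = FALSE)
  attr(df, "ci_disabled") <- !has_counts
  df
}

#' Write / read a trace curve as CSV
#'
#' Columns `t, a_hat, ci_low, ci_high, source`; full stored precision, so the
#' round trip is lossless.
#' @param trace A [trace_curve()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_curve"))
  utils::write.csv(format(as.data.frame(trace), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trace_curve(df$t, as.numeric(df$a_hat), as.numeric(df$ci_low),
              as.numeric(df$ci_high), source = df$source[1])
}

#' Write / read a prevalence surface as long-format CSV
#'
#' Columns `t, a, p` (one row per grid node).  Values are validated to be
#' finite on write; the round trip reconstructs the surface exactly.
#' @param surface A [prevalence_surface()].
#' @param path Output path.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "prevalence_surface"))
  df <- as.data.frame(surface)
  if (any(!is.finite(df$p))) stop("surface contains non-finite values",
                                  call. = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @param provenance Provenance label for the reconstructed surface.
#' @export
read_surface <- function(path, provenance = "external") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- sort(unique(df$t)); as <- sort(unique(df$a))
  vals <- matrix(NA_real_, length(ts), length(as))
  vals[cbind(match(df$t, ts), match(df$a, as))] <- df$p
  prevalence_surface(lexis_grid(ts, as), vals, provenance = provenance)
}

#' Serialise / restore a fitted prevalence model as JSON
#'
#' Versioned schema carrying both the raw-coordinate and the centered
#' coefficients (full IEEE precision), the centering metadata and the fit
#' summary, so `read_model(write_model(m)) ` reproduces the model
#' bit-for-bit.
#' @param model A `prevalence_fit`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prevalence_fit"))
  raw <- coef_raw(model)
  obj <- list(
    schema = "peakdrift-model/1",
    deg_a = model$deg_a, deg_t = model$deg_t,
    t_offset = model$t_offset, a_scale = model$a_scale,
    alpha = model$alpha, beta = model$beta,
    alpha_raw = raw$alpha, beta_raw = raw$beta,
    vcov = model$vcov, converged = model$converged,
    years = model$years, n_cells = model$n_cells,
    deviance = model$deviance, null_deviance = model$null_deviance,
    method = model$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "peakdrift-model/1"))
    stop("unrecognised model schema: ", obj$schema, call. = FALSE)
  V <- obj$vcov
  if (!is.null(V)) {
    V <- as.matrix(V)
    nm <- c(paste0("a", 0:obj$deg_a), paste0("t_a", 0:obj$deg_a))
    dimnames(V) <- list(nm, nm)
  }
  new_prevalence_fit(
    alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
    t_offset = as.numeric(obj$t_offset), deg_a = obj$deg_a,
    a_scale = as.numeric(obj$a_scale),
    vcov = V, converged = isTRUE(obj$converged),
    years = if (is.null(obj$years)) NULL else as.numeric(obj$years),
    n_cells = if (is.null(obj$n_cells)) NA_integer_ else obj$n_cells,
    deviance = if (is.null(obj$deviance)) NA_real_ else obj$deviance,
    null_deviance = if (is.null(obj$null_deviance)) NA_real_
                    else obj$null_deviance,
    method = obj$method)
}
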