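#' Spline basis specification
#'
#' Describes a one-dimensional spline basis used on either side of the
#' cross-basis: a B-spline of arbitrary degree (the exposure dimension;
#' default quadratic) or a natural cubic spline (the lag and calendar-time
#' dimensions). The number of interior knots is tied to the basis dimension
#' `df` by the knot-count rule `df - degree - intercept` for B-splines and
#' `df - 1 - intercept` for natural cubic splines.
#'
#' @param kind `"bspline"` or `"natural_cubic"`.
#' @param df Basis dimension (number of columns the evaluated basis has).
#' @param degree Polynomial degree, B-splines only (default 2, quadratic).
#' @param intercept Logical; keep the full basis (`TRUE`) or drop the
#'   redundant column so the basis can sit next to a model intercept
#'   (`FALSE`).
#' @param internal_knots Ordered interior knots, strictly inside the
#'   boundary interval. Length must satisfy the knot-count rule.
#' @param boundary_knots Length-2 numeric, `lo < hi`.
#' @return An object of class `basis_spec`.
#' @seealso [place_knots()] which derives the knots from data, and
#'   [eval_basis()] which evaluates the basis.
#' @export
basis_spec <- function(kind = c("bspline", "natural_cubic"), df,
                       degree = 2L, intercept = FALSE,
                       internal_knots = numeric(), boundary_knots) {
  kind <- match.arg(kind)
  df <- as.integer(df)
  degree <- as.integer(degree)
  if (df < 1L) stop("infeasible basis: df must be >= 1")
  if (kind == "bspline" && degree < 1L)
    stop("infeasible basis: degree must be >= 1 for a B-spline")
  if (length(boundary_knots) != 2L || !all(is.finite(boundary_knots)) ||
      boundary_knots[1] >= boundary_knots[2])
    stop("boundary_knots must be two finite values with lo < hi")
  n_expected <- n_internal_knots(kind, df, degree, intercept)
  if (n_expected < 0L)
    stop(sprintf(
      "infeasible basis: kind=%s df=%d degree=%d intercept=%s implies %d internal knots",
      kind, df, degree, intercept, n_expected))
  internal_knots <- as.numeric(internal_knots)
  if (length(internal_knots) != n_expected)
    stop(sprintf("expected %d internal knots, got %d",
                 n_expected, length(internal_knots)))
  if (is.unsorted(internal_knots))
    stop("internal_knots must be non-decreasing")
  if (length(internal_knots) &&
      (min(internal_knots) <= boundary_knots[1] ||
       max(internal_knots) >= boundary_knots[2]))
    stop("internal_knots must lie strictly inside the boundary interval")
  structure(
    list(kind = kind, df = df, degree = degree, intercept = intercept,
         internal_knots = internal_knots,
         boundary_knots = as.numeric(boundary_knots)),
    class = "basis_spec")
}

# Knot-count rule: df - degree - intercept for B-splines,
# df - 1 - intercept for natural cubic splines.
n_internal_knots <- function(kind, df, degree, intercept) {
  if (kind == "bspline") df - degree - as.integer(intercept)
  else df - 1L - as.integer(intercept)
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> %s, df=%d%s, intercept=%s\n", x$kind, x$df,
              if (x$kind == "bspline") sprintf(", degree=%d", x$degree) else "",
              x$intercept))
  cat("  boundary:", format(x$boundary_knots), "\n")
  cat("  internal:", if (length(x$internal_knots))
    format(x$internal_knots) else "(none)", "\n")
  invisible(x)
}

#' Place knots from observed values
#'
#' Builds a complete [basis_spec()]: boundary knots at the observed range,
#' interior knots at equally spaced quantiles of `values` (1 knot at the
#' median, 3 knots at the quartiles, ...), with the interior-knot count
#' fixed by the dimension rule (`df - degree - intercept` for B-splines,
#' `df - 1 - intercept` for natural cubic splines).
#'
#' @inheritParams basis_spec
#' @param values Observed values (exposure series, or the integer lag
#'   sequence `0:maxlag`).
#' @return A `basis_spec` with knots filled in.
#' @examples
#' place_knots(0:100, df = 3, kind = "bspline", degree = 2)   # knot at 50
#' place_knots(0:14, df = 5, kind = "natural_cubic", intercept = TRUE)
#' @export
place_knots <- function(values, df, kind = c("bspline", "natural_cubic"),
                        degree = 2L, intercept = FALSE) {
  kind <- match.arg(kind)
  if (!length(values) || !all(is.finite(values)))
    stop("values must be non-empty and finite")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate range: all values identical, cannot place knots")
  n_int <- n_internal_knots(kind, as.integer(df), as.integer(degree), intercept)
  if (n_int < 0L)
    stop(sprintf("infeasible basis: df=%d too small for kind=%s degree=%d intercept=%s",
                 df, kind, degree, intercept))
  internal <- if (n_int > 0L)
    unname(stats::quantile(values, probs = seq_len(n_int) / (n_int + 1),
                           names = FALSE, type = 7))
  else numeric()
  basis_spec(kind, df, degree, intercept, internal, rng)
}

#' Evaluate a spline basis
#'
#' Dispatches to [bspline_basis()] or [natural_cubic_basis()] according to
#' `spec$kind`.
#'
#' @param x Points at which to evaluate (finite numeric).
#' @param spec A [basis_spec()].
#' @return Numeric matrix, `length(x)` rows by `spec$df` columns, with the
#'   spec attached as attribute `"spec"`.
#' @export
eval_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  switch(spec$kind,
         bspline = bspline_basis(x, spec),
         natural_cubic = natural_cubic_basis(x, spec))
}

#' B-spline basis (Cox--de Boor)
#'
#' Evaluates the B-spline basis on the padded knot sequence (boundary knots
#' repeated `degree + 1` times). Inside the boundary this is
#' `splines::splineDesign()`; outside, each basis function is continued by
#' the exact polynomial of the terminal span, reconstructed from its
#' derivatives at the boundary (a degree-`degree` Taylor expansion, which is
#' exact for a piecewise polynomial). With `intercept = FALSE` the first
#' basis column is dropped.
#'
#' @inheritParams eval_basis
#' @export
bspline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"), spec$kind == "bspline")
  if (!all(is.finite(x))) stop("non-finite values in x")
  d <- spec$degree
  lo <- spec$boundary_knots[1]
  hi <- spec$boundary_knots[2]
  kn <- c(rep(lo, d + 1L), spec$internal_knots, rep(hi, d + 1L))
  nb <- length(kn) - d - 1L   # full basis dimension
  B <- matrix(0, length(x), nb)
  inside <- x >= lo & x <= hi
  if (any(inside))
    B[inside, ] <- splines::splineDesign(kn, x[inside], ord = d + 1L)
  for (side in c(-1, 1)) {
    out <- if (side < 0) x < lo else x > hi
    if (!any(out)) next
    b <- if (side < 0) lo else hi
    h <- x[out] - b
    acc <- matrix(0, sum(out), nb)
    for (k in 0:d) {
      Dk <- drop(splines::splineDesign(kn, b, ord = d + 1L, derivs = k))
      acc <- acc + outer(h^k, Dk) / factorial(k)
    }
    B[out, ] <- acc
  }
  if (!spec$intercept) B <- B[, -1L, drop = FALSE]
  dimnames(B) <- list(NULL, paste0("b", seq_len(ncol(B))))
  structure(B, spec = spec, eval_points = as.numeric(x))
}

#' Natural cubic spline basis
#'
#' Cubic spline basis constrained to zero second derivative at the boundary
#' knots and linear continuation beyond them (via `splines::ns`). Dimension
#' is `length(internal_knots) + 1 + intercept`.
#'
#' @inheritParams eval_basis
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"), spec$kind == "natural_cubic")
  if (!all(is.finite(x))) stop("non-finite values in x")
  kn <- if (length(spec$internal_knots)) spec$internal_knots else NULL
  N <- splines::ns(x, knots = kn, Boundary.knots = spec$boundary_knots,
                   intercept = spec$intercept)
  B <- matrix(as.numeric(N), nrow = length(x))
  stopifnot(ncol(B) == spec$df)
  dimnames(B) <- list(NULL, paste0("b", seq_len(ncol(B))))
  structure(B, spec = spec, eval_points = as.numeric(x))
}

#' Seasonal/long-term trend spline over calendar time
#'
#' Natural cubic basis of the day index with a total dimension of
#' `round(df_per_year * n_days / days_per_year)` (default 7 df per year of
#' data, `days_per_year = 365.25`), or exactly `total_df` when given.
#' Knots at equally spaced quantiles of the day index.
#'
#' @param day_index Consecutive integer day indices.
#' @param df_per_year Spline dimension per year of data.
#' @param days_per_year Length of a year used in the conversion.
#' @param total_df Override: use exactly this total dimension.
#' @return Basis matrix (no intercept column; pair with a model intercept).
#' @export
time_spline <- function(day_index, df_per_year = 7, days_per_year = 365.25,
                        total_df = NULL) {
  if (length(day_index) < 2L || any(diff(day_index) != 1L))
    stop("day_index must be consecutive integers")
  df <- if (is.null(total_df))
    as.integer(round(df_per_year * length(day_index) / days_per_year))
  else as.integer(total_df)
  if (df < 1L) stop("total time-spline df < 1; supply more data or a larger df_per_year")
  spec <- place_knots(day_index, df = df, kind = "natural_cubic",
                      intercept = FALSE)
  B <- natural_cubic_basis(day_index, spec)
  dimnames(B) <- list(NULL, paste0("time", seq_len(ncol(B))))
  B
}

#' Day-of-week indicator columns
#'
#' Six dummy columns with a fixed reference weekday (default Monday): a row
#' is all zero exactly when the date falls on the reference day. Relative
#' risks downstream are invariant to the reference choice.
#'
#' @param dates `Date` vector.
#' @param ref Reference weekday, one of `"Mon" ... "Sun"`.
#' @return Numeric matrix with 6 columns `dow_<day>`.
#' @export
dow_indicators <- function(dates, ref = "Mon") {
  dates <- as.Date(dates)
  labs <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  ref <- match.arg(ref, c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  wd <- labs[as.POSIXlt(dates)$wday + 1L]   # locale-independent
  lev <- c(ref, setdiff(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), ref))
  f <- factor(wd, levels = lev)
  M <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  dimnames(M) <- list(NULL, paste0("dow_", lev[-1L]))
  M
}
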