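#' Lagged exposure matrix
#'
#' Column `l + 1` holds the exposure `l` days before each row's day
#' (lag 0 = same day). Rows without a complete lag history (the first
#' `maxlag` days) carry `NA` in the incomplete cells.
#'
#' @param series Numeric exposure series, one value per day.
#' @param maxlag Maximum lag in days (>= 0).
#' @return A `length(series)` by `maxlag + 1` matrix with columns
#'   `lag0 ... lag<maxlag>` and attribute `valid_from` (first 1-based row
#'   with complete history, `maxlag + 1`).
#' @export
lag_matrix <- function(series, maxlag) {
  maxlag <- as.integer(maxlag)
  n <- length(series)
  if (maxlag < 0L) stop("maxlag must be >= 0")
  if (n <= maxlag) stop("series must be longer than maxlag")
  Q <- matrix(NA_real_, n, maxlag + 1L)
  for (l in 0:maxlag)
    Q[(l + 1L):n, l + 1L] <- series[seq_len(n - l)]
  dimnames(Q) <- list(NULL, paste0("lag", 0:maxlag))
  structure(Q, maxlag = maxlag, valid_from = maxlag + 1L)
}

#' Cross-basis design matrix
#'
#' The bidimensional exposure-lag design block: for exposure basis functions
#' `R_j` (default quadratic B-spline, df 3, knots from the observed exposure
#' distribution) and lag basis functions `C_k` (default natural cubic, df 5
#' with intercept, knots from the integer lag sequence),
#' \deqn{cb[t, (j,k)] = \sum_{l=0}^{L} R_j(x_{t-l}) \, C_k(l).}
#' Columns are ordered j-major (`cb_1_1, cb_1_2, ..., cb_1_vl, cb_2_1, ...`).
#' Rows without complete lag history (the first `maxlag` days) are `NA` and
#' must be excluded from fitting.
#'
#' @param series Daily exposure values.
#' @param maxlag Maximum lag in days (default 14).
#' @param var_spec,lag_spec Optional [basis_spec()] overrides for the
#'   exposure and lag dimensions; by default they are placed from the data
#'   via [place_knots()] with `var_df`/`var_degree` and `lag_df`.
#' @param var_df,var_degree,lag_df Dimensions used when specs are derived
#'   from the data (defaults 3, 2 and 5).
#' @return An object of class `crossbasis`: list with the design `matrix`
#'   (T x `var_df * lag_df`), the two specs, `maxlag`, column `labels`
#'   `cb_<j>_<k>`, and the originating `series`.
#' @export
build_crossbasis <- function(series, maxlag = 14L, var_spec = NULL,
                             lag_spec = NULL, var_df = 3L, var_degree = 2L,
                             lag_df = 5L) {
  maxlag <- as.integer(maxlag)
  if (is.null(var_spec))
    var_spec <- place_knots(series, df = var_df, kind = "bspline",
                            degree = var_degree, intercept = FALSE)
  if (is.null(lag_spec))
    lag_spec <- place_knots(0:maxlag, df = lag_df, kind = "natural_cubic",
                            intercept = TRUE)
  Q <- lag_matrix(series, maxlag)
  C <- eval_basis(0:maxlag, lag_spec)               # (L+1) x vl
  vx <- var_spec$df
  vl <- lag_spec$df
  n <- length(series)
  ok <- seq.int(maxlag + 1L, n)                     # complete-history rows
  Rall <- eval_basis(as.vector(Q[ok, , drop = FALSE]), var_spec)
  M <- matrix(NA_real_, n, vx * vl)
  for (j in seq_len(vx)) {
    Rj <- matrix(Rall[, j], nrow = length(ok))      # T' x (L+1)
    M[ok, (j - 1L) * vl + seq_len(vl)] <- Rj %*% C
  }
  labels <- paste0("cb_", rep(seq_len(vx), each = vl), "_", rep(seq_len(vl), vx))
  colnames(M) <- labels
  structure(
    list(matrix = M, var_spec = var_spec, lag_spec = lag_spec,
         maxlag = maxlag, labels = labels, series = as.numeric(series)),
    class = "crossbasis")
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("<crossbasis> %d days x %d columns (exposure df %d x lag df %d), maxlag %d\n",
              nrow(x$matrix), ncol(x$matrix), x$var_spec$df, x$lag_spec$df,
              x$maxlag))
  invisible(x)
}

#' Rows of a cross-basis with complete lag history
#'
#' Logical mask that is `FALSE` for the first `maxlag` rows.
#' @param cb A [build_crossbasis()] object.
#' @export
complete_rows <- function(cb) {
  stopifnot(inherits(cb, "crossbasis"))
  seq_len(nrow(cb$matrix)) > cb$maxlag
}

#' Write a cross-basis design block to CSV
#'
#' Labeled export (`cb_<j>_<k>` columns) for debugging and cross-language
#' parity checks.
#' @param cb A `crossbasis` object.
#' @param path Output file.
#' @export
write_crossbasis_csv <- function(cb, path) {
  stopifnot(inherits(cb, "crossbasis"))
  utils::write.csv(as.data.frame(cb$matrix), path, row.names = FALSE)
  invisible(path)
}
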