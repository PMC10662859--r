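#' Relative-risk surface from a fitted cross-basis model
#'
#' Turns coefficients of the cross-basis columns into lag-specific and
#' lag-cumulative log relative risks on an exposure grid, relative to a
#' centering exposure. For grid value `x` and lag `l` the contrast vector
#' has entries \eqn{(R_j(x) - R_j(c)) C_k(l)} over the cross-basis columns;
#' the log RR is its inner product with the coefficients and the variance
#' the corresponding quadratic form in the covariance (delta method).
#' Cumulative quantities over lags `0..L'` use the summed contrast.
#'
#' @param fit A [fit_quasipoisson()] result whose design contained the
#'   cross-basis columns (matched by label).
#' @param cb The [build_crossbasis()] object.
#' @param exposure_grid Exposure values at which to evaluate.
#' @param center Centering exposure (RR = 1 there by construction).
#' @param level Confidence level (default 0.95).
#' @return An object of class `rr_surface`: `exposure_grid`, `lags`,
#'   matrices `log_rr`, `se`, `cum_log_rr`, `cum_se` (grid x lags; the
#'   cumulative column for lag `L'` covers lags `0..L'`), `center`, `level`.
#' @export
predict_rr <- function(fit, cb, exposure_grid, center, level = 0.95) {
  stopifnot(inherits(fit, "qp_fit"), inherits(cb, "crossbasis"))
  idx <- match(cb$labels, fit$labels)
  if (anyNA(idx))
    stop("label mismatch: cross-basis columns ",
         paste(cb$labels[is.na(idx)], collapse = ", "),
         " not found in the fit")
  beta <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]

  vx <- cb$var_spec$df
  vl <- cb$lag_spec$df
  L1 <- cb$maxlag + 1L
  G <- length(exposure_grid)
  A <- eval_basis(exposure_grid, cb$var_spec) -
    matrix(eval_basis(center, cb$var_spec), G, vx, byrow = TRUE)
  C <- eval_basis(0:cb$maxlag, cb$lag_spec)         # L1 x vl

  jj <- rep(seq_len(vx), each = vl)                 # j-major column layout
  kk <- rep(seq_len(vl), vx)
  log_rr <- se <- cum_log_rr <- cum_se <- matrix(NA_real_, G, L1)
  Zcum <- matrix(0, G, vx * vl)
  for (l in seq_len(L1)) {
    Zl <- A[, jj, drop = FALSE] *
      matrix(C[l, kk], G, vx * vl, byrow = TRUE)
    log_rr[, l] <- Zl %*% beta
    se[, l] <- sqrt(pmax(rowSums((Zl %*% V) * Zl), 0))
    Zcum <- Zcum + Zl
    cum_log_rr[, l] <- Zcum %*% beta
    cum_se[, l] <- sqrt(pmax(rowSums((Zcum %*% V) * Zcum), 0))
  }
  dn <- list(NULL, paste0("lag", 0:cb$maxlag))
  dimnames(log_rr) <- dimnames(se) <- dn
  dimnames(cum_log_rr) <- dimnames(cum_se) <-
    list(NULL, paste0("lag0_", 0:cb$maxlag))
  structure(
    list(exposure_grid = as.numeric(exposure_grid), lags = 0:cb$maxlag,
         log_rr = log_rr, se = se, cum_log_rr = cum_log_rr, cum_se = cum_se,
         center = center, level = level),
    class = "rr_surface")
}

#' @export
print.rr_surface <- function(x, ...) {
  cat(sprintf("<rr_surface> %d exposure values x lags 0..%d, centered at %g\n",
              length(x$exposure_grid), max(x$lags), x$center))
  invisible(x)
}

#' Minimum-risk centering value
#'
#' Two-pass search for the exposure value used as the RR reference: the
#' overall cumulative (lag 0..L) curve is predicted with a provisional
#' center at the observed exposure median, and the grid value minimizing
#' that curve is returned. Re-centering at the returned value makes it the
#' curve's argmin with RR = 1. A flat curve (range below 1e-12) returns the
#' median with a warning.
#'
#' @inheritParams predict_rr
#' @param search_grid Grid to search; default 100 equally spaced points over
#'   the observed exposure range.
#' @param grid_points Size of the default grid.
#' @return The minimizing exposure value (scalar).
#' @export
find_min_risk <- function(fit, cb, search_grid = NULL, grid_points = 100L) {
  stopifnot(inherits(cb, "crossbasis"))
  rng <- range(cb$series)
  if (is.null(search_grid))
    search_grid <- seq(rng[1], rng[2], length.out = grid_points)
  provisional <- stats::median(cb$series)
  surf <- predict_rr(fit, cb, search_grid, center = provisional)
  overall <- surf$cum_log_rr[, ncol(surf$cum_log_rr)]
  if (diff(range(overall)) < 1e-12) {
    warning("overall cumulative curve is flat; returning the exposure median")
    return(provisional)
  }
  search_grid[which.min(overall)]
}

#' Tidy relative-risk table
#'
#' Long-format table of lag-specific and lag-cumulative relative risks with
#' Wald confidence intervals, at a named set of exposure values (e.g. min,
#' deciles, max, mode). `significant` flags intervals excluding 1 (two-sided
#' at `level`).
#'
#' @param surface An [predict_rr()] `rr_surface` whose grid contains every
#'   requested value.
#' @param at Named numeric vector of exposure values.
#' @param level Confidence level; default the surface's.
#' @return A tibble with columns `value_name`, `factor_value`, `type`
#'   (`"lag"` for single lags, `"cumulative"` for lags 0..`lag`), `lag`,
#'   `rr`, `ci_lo`, `ci_hi`, `significant`.
#' @export
rr_table <- function(surface, at, level = NULL) {
  stopifnot(inherits(surface, "rr_surface"))
  if (is.null(level)) level <- surface$level
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- vapply(at, function(v) {
    i <- which(abs(surface$exposure_grid - v) < 1e-9)[1]
    if (is.na(i)) stop(sprintf("requested value %g is not on the surface grid", v))
    i
  }, integer(1))
  L1 <- length(surface$lags)
  one <- function(est, sd, type) {
    tibble::tibble(
      value_name = rep(names(at), each = L1),
      factor_value = rep(unname(at), each = L1),
      type = type,
      lag = rep(surface$lags, length(at)),
      rr = exp(as.vector(t(est[rows, , drop = FALSE]))),
      ci_lo = exp(as.vector(t(est[rows, , drop = FALSE] -
                                z * sd[rows, , drop = FALSE]))),
      ci_hi = exp(as.vector(t(est[rows, , drop = FALSE] +
                                z * sd[rows, , drop = FALSE]))))
  }
  out <- rbind(one(surface$log_rr, surface$se, "lag"),
               one(surface$cum_log_rr, surface$cum_se, "cumulative"))
  out$significant <- out$ci_lo > 1 | out$ci_hi < 1
  out
}
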