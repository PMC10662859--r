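#' Quasi-Poisson regression by IRLS
#'
#' Fits a log-linear count regression by iteratively reweighted least
#' squares: the coefficients maximize the Poisson log-likelihood, and the
#' dispersion is estimated afterwards from the Pearson statistic,
#' \eqn{\phi = \sum (y-\hat\mu)^2/\hat\mu \, / \, (n - p)}, which scales the
#' covariance \eqn{\phi (X^\top \hat W X)^{-1}} with \eqn{\hat W =
#' \mathrm{diag}(\hat\mu)}. Each weighted least-squares step is solved via a
#' QR decomposition of the weighted design (not normal equations), which
#' matters for the long, nearly collinear seasonal splines used here.
#' Starting values are \eqn{\mu^{(0)} = y + 0.5}, safe with many zero-count
#' days.
#'
#' @param y Non-negative integer counts.
#' @param X Design matrix (should include an intercept column); must be of
#'   full column rank on the kept rows.
#' @param row_mask Logical vector marking rows to fit (e.g. drop the
#'   incomplete-lag-history rows); default keeps rows with no `NA` in `X`.
#' @param tol Convergence tolerance on the relative deviance change
#'   (default 1e-10).
#' @param maxit Iteration cap (default 100); non-convergence is flagged,
#'   not an error.
#' @return An object of class `qp_fit`: `coefficients`, `vcov`,
#'   `dispersion`, `deviance`, `fitted` (full-length, `NA` on masked rows),
#'   `n_obs`, `n_params`, `labels`, `converged`, `n_iter`, `row_mask`.
#' @export
fit_quasipoisson <- function(y, X, row_mask = NULL, tol = 1e-10, maxit = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(row_mask)) row_mask <- stats::complete.cases(X) & !is.na(y)
  stopifnot(length(row_mask) == nrow(X), length(y) == nrow(X))
  ym <- y[row_mask]
  Xm <- X[row_mask, , drop = FALSE]
  if (any(ym < 0) || any(ym != round(ym)))
    stop("y must contain non-negative integer counts")
  n <- length(ym)
  p <- ncol(Xm)
  if (n <= p) stop("more parameters than observations")
  q0 <- qr(Xm)
  if (q0$rank < p)
    stop("singular design: column(s) ",
         paste(colnames(Xm)[q0$pivot[(q0$rank + 1L):p]], collapse = ", "),
         " are linearly dependent on the others")

  mu <- ym + 0.5
  eta <- log(mu)
  dev <- poisson_deviance(ym, mu)
  beta <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    w <- mu
    z <- eta + (ym - mu) / mu
    fit <- stats::lm.wfit(Xm, z, w)
    beta <- fit$coefficients
    eta <- drop(Xm %*% beta)
    mu <- exp(eta)
    dev_new <- poisson_deviance(ym, mu)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) <= tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  phi <- pearson_dispersion(ym, mu, p)
  qw <- qr(Xm * sqrt(mu))
  cov_unscaled <- matrix(NA_real_, p, p)
  piv <- qw$pivot
  cov_unscaled[piv, piv] <- chol2inv(qr.R(qw))
  vcov <- phi * cov_unscaled
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(Xm), colnames(Xm))
  names(beta) <- colnames(Xm)

  fitted <- rep(NA_real_, nrow(X))
  fitted[row_mask] <- mu
  structure(
    list(coefficients = beta, vcov = vcov, dispersion = phi, deviance = dev,
         fitted = fitted, n_obs = n, n_params = p, labels = colnames(Xm),
         converged = converged, n_iter = iter, row_mask = row_mask),
    class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("<qp_fit> %d obs, %d params, dispersion %.3f, deviance %.2f (%s in %d iter)\n",
              x$n_obs, x$n_params, x$dispersion, x$deviance,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# Poisson deviance with the y = 0 limit handled (y log y -> 0).
poisson_deviance <- function(y, mu) {
  r <- y * log(ifelse(y > 0, y / mu, 1)) - (y - mu)
  2 * sum(r)
}

#' Pearson dispersion estimate
#'
#' \eqn{\phi = \sum_i (y_i - \mu_i)^2 / \mu_i \; / \; (n - p)}.
#'
#' @param y Observed counts.
#' @param mu Fitted means (> 0).
#' @param n_params Number of fitted parameters `p`.
#' @export
pearson_dispersion <- function(y, mu, n_params) {
  stopifnot(length(y) == length(mu))
  if (any(mu <= 0)) stop("mu must be positive")
  n <- length(y)
  if (n <= n_params) stop("n must exceed n_params")
  sum((y - mu)^2 / mu) / (n - n_params)
}
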