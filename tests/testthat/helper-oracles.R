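# Independent oracles, written before the implementations they check and
# deliberately naive: direct recursions and explicit loops, no shared code
# with the package internals.

# Naive Cox–de Boor recursion on the padded knot sequence of a spec.
# Right-closed convention at the last knot so the upper boundary evaluates
# to the limit from the left.
naive_bspline <- function(x, spec) {
  d <- spec$degree
  kn <- c(rep(spec$boundary_knots[1], d + 1), spec$internal_knots,
          rep(spec$boundary_knots[2], d + 1))
  last <- kn[length(kn)]
  Bi <- function(i, deg, t) {
    if (deg == 0) {
      inside <- kn[i] <= t & t < kn[i + 1]
      closed <- t == last & kn[i] < kn[i + 1] & kn[i + 1] == last
      return(as.numeric(inside | closed))
    }
    w1 <- if (kn[i + deg] > kn[i]) (t - kn[i]) / (kn[i + deg] - kn[i]) else 0
    w2 <- if (kn[i + deg + 1] > kn[i + 1])
      (kn[i + deg + 1] - t) / (kn[i + deg + 1] - kn[i + 1]) else 0
    w1 * Bi(i, deg - 1, t) + w2 * Bi(i + 1, deg - 1, t)
  }
  nb <- length(kn) - d - 1
  B <- sapply(seq_len(nb), function(i) sapply(x, function(t) Bi(i, d, t)))
  B <- matrix(B, nrow = length(x))
  if (!spec$intercept) B <- B[, -1, drop = FALSE]
  B
}

# Brute-force cross-basis: explicit loops over (t, lag, j, k).
brute_crossbasis <- function(series, maxlag, var_spec, lag_spec) {
  n <- length(series)
  vx <- var_spec$df
  vl <- lag_spec$df
  R <- eval_basis(series, var_spec)
  C <- eval_basis(0:maxlag, lag_spec)
  M <- matrix(NA_real_, n, vx * vl)
  for (t in (maxlag + 1):n) {
    for (j in 1:vx) {
      for (k in 1:vl) {
        acc <- 0
        for (l in 0:maxlag) acc <- acc + R[t - l, j] * C[l + 1, k]
        M[t, (j - 1) * vl + k] <- acc
      }
    }
  }
  M
}

# Direct Newton-Raphson maximization of the Poisson log-likelihood
# (log link), from beta = 0, solving the normal equations directly.
newton_poisson <- function(y, X, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Numerical second derivative by central differences.
num_d2 <- function(f, x, h = 1e-4) (f(x + h) - 2 * f(x) + f(x - h)) / h^2

# Small simulated study shared by several tests (3 years, temperature-like
# exposure, known quadratic-x-decay surface).
make_small_study <- function(n_days = 1096, seed = 42,
                             surface = true_surface(),
                             baseline = baseline_spec(dispersion = 1),
                             dow_effects = TRUE) {
  if (!dow_effects) baseline$dow_log_effects[] <- 0
  simulate_study(n_days = n_days, seed = seed, surface = surface,
                 baseline = baseline)
}
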