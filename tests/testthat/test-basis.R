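test_that("knot placement follows the dimension rule and quantile convention", {
  # quadratic B-spline, df 3, no intercept: 3 - 2 - 0 = 1 knot at the median
  s <- place_knots(0:100, df = 3, kind = "bspline", degree = 2)
  expect_equal(s$internal_knots, 50)
  expect_equal(s$boundary_knots, c(0, 100))

  # natural cubic, df 5 with intercept: 5 - 1 - 1 = 3 knots at the quartiles
  s2 <- place_knots(0:14, df = 5, kind = "natural_cubic", intercept = TRUE)
  expect_equal(s2$internal_knots, c(3.5, 7, 10.5))

  # boundary knots are exactly the observed range
  v <- c(-3.2, 7.7, runif(50, -3, 7))
  s3 <- place_knots(v, df = 4, kind = "natural_cubic")
  expect_identical(s3$boundary_knots, range(v))

  # property: knot counts over feasible combinations
  for (df in 1:7) for (ic in c(FALSE, TRUE)) {
    for (deg in 1:3) {
      n_int <- df - deg - ic
      if (n_int >= 0) {
        s <- place_knots(1:50, df, "bspline", deg, ic)
        expect_length(s$internal_knots, n_int)
      } else {
        expect_error(place_knots(1:50, df, "bspline", deg, ic), "infeasible")
      }
    }
    n_int <- df - 1 - ic
    if (n_int >= 0)
      expect_length(place_knots(1:50, df, "natural_cubic",
                                intercept = ic)$internal_knots, n_int)
    else
      expect_error(place_knots(1:50, df, "natural_cubic", intercept = ic),
                   "infeasible")
  }

  expect_error(place_knots(rep(3, 10), df = 3, kind = "bspline"),
               "degenerate range")
})

test_that("B-spline basis matches the naive Cox-de Boor recursion", {
  set.seed(7)
  for (rep in 1:20) {
    df <- sample(3:6, 1)
    deg <- sample(1:3, 1)
    ic <- sample(c(TRUE, FALSE), 1)
    if (df - deg - ic < 0) next
    v <- sort(runif(60))
    s <- place_knots(v, df, "bspline", deg, ic)
    x <- runif(10, min(v), max(v))
    expect_lt(max(abs(eval_basis(x, s) - naive_bspline(x, s))), 1e-10)
  }
})

test_that("full B-spline basis is a partition of unity inside the boundary", {
  s <- place_knots(runif(200, 0, 30), df = 5, kind = "bspline",
                   degree = 2, intercept = TRUE)
  B <- eval_basis(seq(0, 30, length.out = 101), s)
  expect_equal(rowSums(B), rep(1, 101), tolerance = 1e-12)
  expect_true(all(is.finite(B)))
})

test_that("B-spline extrapolation continues the terminal polynomial pieces", {
  s <- place_knots(0:20, df = 4, kind = "bspline", degree = 2)
  # a quadratic spline extended beyond the boundary stays a quadratic:
  # third finite difference of any basis column is zero out there
  for (b in list(c(21, 22, 23, 24), c(-4, -3, -2, -1))) {
    B <- eval_basis(b, s)
    d3 <- B[4, ] - 3 * B[3, ] + 3 * B[2, ] - B[1, ]
    expect_lt(max(abs(d3)), 1e-8)
  }
  # and it is continuous at the boundary
  eps <- 1e-9
  expect_lt(max(abs(eval_basis(20 + eps, s) - eval_basis(20, s))), 1e-6)
})

test_that("natural cubic basis: boundary curvature, linear tails, span", {
  s <- place_knots(0:14, df = 5, kind = "natural_cubic", intercept = TRUE)
  B <- eval_basis(0:14, s)
  expect_equal(ncol(B), 5)
  expect_equal(qr(B)$rank, 5)

  set.seed(11)
  co <- rnorm(5)
  f <- function(x) drop(eval_basis(x, s) %*% co)
  # second derivative vanishes at both boundary knots; the plain central
  # difference at a boundary carries a one-sided O(h) cubic term, so use
  # its Richardson extrapolation 2 D(h) - D(2h), which cancels it
  d2 <- function(x, h = 1e-4) 2 * num_d2(f, x, h) - num_d2(f, x, 2 * h)
  expect_lt(abs(d2(0)), 1e-6)
  expect_lt(abs(d2(14)), 1e-6)
  # affine beyond the boundary: zero second difference
  for (b in c(16, 20, -3)) {
    h <- 0.7
    expect_lt(abs(f(b + 2 * h) - 2 * f(b + h) + f(b)), 1e-8)
  }
  # span contains constants and linear functions
  x <- seq(0, 14, length.out = 57)
  Bx <- eval_basis(x, s)
  for (target in list(rep(1, 57), x)) {
    res <- stats::lsfit(Bx, target, intercept = FALSE)$residuals
    expect_lt(max(abs(res)), 1e-8)
  }
})

test_that("time spline df follows the per-year rule", {
  expect_equal(ncol(time_spline(1:4078, df_per_year = 7)), 78)  # round(7*4078/365.25)
  expect_equal(ncol(time_spline(1:365, df_per_year = 7)), 7)
  expect_equal(ncol(time_spline(1:4078, total_df = 84)), 84)    # fixed 7*12 reading
  expect_error(time_spline(c(1, 3, 4)), "consecutive")
  expect_error(time_spline(1:20, df_per_year = 7), "df < 1")
})

test_that("day-of-week indicators behave at the reference and over full weeks", {
  dates <- seq(as.Date("2023-01-02"), by = "day", length.out = 14)  # a Monday
  M <- dow_indicators(dates)
  expect_equal(dim(M), c(14, 6))
  expect_equal(unname(M[1, ]), rep(0, 6))          # Monday = reference
  expect_equal(sum(M[7, ]), 1)                     # a Sunday: exactly one 1
  expect_equal(unname(colSums(M)), rep(2, 6))      # two full weeks
})
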