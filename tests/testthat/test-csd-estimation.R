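# MVAR fitting and analytic spectra.

test_that("fit_mvar recovers AR(1) coefficients and white-noise limits", {
  set.seed(101)
  n <- 4000
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  m <- fit_mvar(cbind(x, rnorm(n)), order = 1, dt = 1)
  se <- sqrt(1 / n / (1 - 0.5^2))        # OLS standard error of an AR(1)
  expect_lt(abs(m$A[[1]][1, 1] - 0.5), 3 * se)

  # white noise: all lag coefficients near zero, Sigma near sample covariance
  set.seed(102)
  W <- matrix(rnorm(3 * 3000), ncol = 3)
  mw <- fit_mvar(W, order = 2, dt = 1)
  expect_lt(max(abs(unlist(mw$A))), 4 / sqrt(3000))
  expect_equal(mw$Sigma, cov(W), tolerance = 0.05, ignore_attr = TRUE)

  # the default order is 8
  m8 <- fit_mvar(W, dt = 1)
  expect_length(m8$A, 8)
  expect_error(fit_mvar(W[1:10, ], dt = 1), "time points")
  expect_error(fit_mvar(W, dt = -1), "positive")
})

test_that("fit_mvar agrees with stats::ar.ols on the same data", {
  set.seed(103)
  n <- 3000
  e <- matrix(rnorm(2 * n), ncol = 2)
  Y <- matrix(0, n, 2)
  A1 <- matrix(c(0.5, 0.1, -0.2, 0.3), 2, 2)
  for (t in 2:n) Y[t, ] <- A1 %*% Y[t - 1, ] + e[t, ]
  ours <- fit_mvar(Y, order = 1, dt = 1)
  ref <- stats::ar.ols(Y, aic = FALSE, order.max = 1, demean = TRUE,
                       intercept = FALSE)
  expect_equal(ours$A[[1]], ref$ar[1, , ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mvar_csd white-noise and AR(1) closed forms hold", {
  # all A_k = 0, Sigma = I, dt = 1: flat one-sided spectrum 2 I
  m <- structure(list(A = list(matrix(0, 2, 2)), Sigma = diag(2), order = 1L,
                      dt = 1, labels = c("a", "b")), class = "mvar_model")
  f <- frequency_grid(0.05, 0.5, 8)
  S <- mvar_csd(m, f)
  for (k in 1:8) expect_equal(S$values[k, , ], 2 * diag(2) + 0i,
                              ignore_attr = TRUE)

  # scalar AR(1)
  a <- 0.6; s2 <- 1.7; dt <- 0.5
  m1 <- structure(list(A = list(matrix(a, 1, 1)), Sigma = matrix(s2, 1, 1),
                       order = 1L, dt = dt, labels = "x"),
                  class = "mvar_model")
  f <- frequency_grid(0.01, 1 / (2 * dt), 16)
  S1 <- mvar_csd(m1, f)
  closed <- 2 * dt * s2 / Mod(1 - a * exp(-2i * pi * as.numeric(f) * dt))^2
  expect_equal(Re(S1$values[, 1, 1]), closed, tolerance = 1e-12)

  # Parseval: integral of the one-sided density over (0, Nyquist] equals
  # the process variance s2/(1-a^2)
  dens <- function(f) 2 * dt * s2 / Mod(1 - a * exp(-2i * pi * f * dt))^2
  integral <- stats::integrate(dens, 0, 1 / (2 * dt), rel.tol = 1e-10)$value
  expect_equal(integral, s2 / (1 - a^2), tolerance = 1e-8)

  # nonstationary models are refused
  bad <- structure(list(A = list(matrix(1.05, 1, 1)), Sigma = diag(1),
                        order = 1L, dt = 1, labels = "x"),
                   class = "mvar_model")
  expect_error(mvar_csd(bad, frequency_grid(0.05, 0.5, 4)), "nonstationary")
  expect_error(mvar_csd(m1, frequency_grid(0.5, 2, 4)), "Nyquist")
})

test_that("estimate_csd is deterministic and output is Hermitian PSD", {
  set.seed(104)
  Y <- matrix(rnorm(600), ncol = 3)
  f <- frequency_grid(0.02, 0.4, 12)
  S1 <- estimate_csd(Y, f, dt = 1)
  S2 <- estimate_csd(Y, f, dt = 1)
  expect_identical(S1$values, S2$values)
  expect_hermitian_psd(S1)
})

test_that("estimated spectra converge to the generating MVAR's spectrum", {
  A1 <- matrix(c(0.5, 0.1, 0, 0.3), 2, 2)
  A2 <- matrix(c(-0.2, 0, 0.05, 0.1), 2, 2)
  Sig <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  gen <- structure(list(A = list(A1, A2), Sigma = Sig, order = 2L, dt = 1,
                        labels = c("a", "b")), class = "mvar_model")
  f <- frequency_grid(0.02, 0.48, 16)
  S_true <- mvar_csd(gen, f)

  simulate_mvar <- function(n, seed) {
    set.seed(seed)
    L <- chol(Sig)
    Y <- matrix(0, n, 2)
    for (t in 3:n) {
      Y[t, ] <- A1 %*% Y[t - 1, ] + A2 %*% Y[t - 2, ] +
        drop(rnorm(2) %*% L)
    }
    Y[-(1:200), ]
  }
  err <- vapply(c(4000, 32000), function(n) {
    S_hat <- estimate_csd(simulate_mvar(n + 200, 105), f, order = 2, dt = 1)
    rel_frobenius(S_hat$values, S_true$values)
  }, numeric(1))
  expect_lt(err[2], 0.05)     # long series: within 5 percent
  expect_lt(err[2], err[1])   # error shrinks with sample size
})

test_that("estimate_csd agrees with smoothed periodograms within sampling error", {
  set.seed(106)
  n <- 8192
  e <- matrix(rnorm(2 * n), ncol = 2)
  Y <- matrix(0, n, 2)
  A1 <- matrix(c(0.6, 0.2, -0.1, 0.4), 2, 2)
  for (t in 2:n) Y[t, ] <- A1 %*% Y[t - 1, ] + e[t, ]
  f <- frequency_grid(0.05, 0.45, 9)
  S <- estimate_csd(Y, f, dt = 1)
  for (ch in 1:2) {
    ps <- stats::spec.pgram(stats::ts(Y[, ch]), spans = c(25, 25),
                            plot = FALSE, detrend = TRUE)
    idx <- vapply(as.numeric(f), function(x) which.min(abs(ps$freq - x)),
                  integer(1))
    # one-sided density is twice R's spectrum estimate
    ratio <- Re(S$values[, ch, ch]) / (2 * ps$spec[idx])
    expect_lt(stats::median(abs(log(ratio))), 0.15)
  }
})

test_that("fit_mvar is channel-permutation equivariant and scale covariant", {
  set.seed(107)
  Y <- matrix(rnorm(900), ncol = 3)
  Y[-1, ] <- Y[-1, ] + 0.4 * Y[-nrow(Y), ]
  m <- fit_mvar(Y, order = 2, dt = 1)
  perm <- c(3, 1, 2)
  mp <- fit_mvar(Y[, perm], order = 2, dt = 1)
  expect_equal(mp$A[[1]], m$A[[1]][perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mp$Sigma, m$Sigma[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)

  s <- c(2, 0.5, 10)
  ms <- fit_mvar(sweep(Y, 2, s, `*`), order = 2, dt = 1)
  D <- diag(s)
  expect_equal(ms$A[[1]], D %*% m$A[[1]] %*% solve(D), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ms$Sigma, D %*% m$Sigma %*% D, tolerance = 1e-8,
               ignore_attr = TRUE)
})
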