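# Feature vectorization, parameter Jacobians, free energy and the
# Gauss-Newton variational scheme.

test_that("CSD vectorization stacks Re/Im deterministically and round-trips", {
  m <- assemble_circuit(matrix(0, 3, 3))
  f <- frequency_grid(n = 32)
  S <- predict_csd(m, frequencies = f)
  x <- vectorize_csd(S)
  expect_length(x, 2 * 32 * 9)        # 576 features
  S2 <- devectorize_csd(x, S$frequencies, S$labels)
  expect_equal(S2$values, S$values)

  # Hermitian diagonal contributes zeros to the imaginary block
  half <- length(x) / 2
  im <- array(x[half + seq_len(half)], c(32, 3, 3))
  for (ch in 1:3) expect_equal(im[, ch, ch], rep(0, 32))
})

test_that("parameter Jacobian respects the tunable mask and known columns", {
  m <- assemble_circuit(matrix(0, 2, 2))
  f <- frequency_grid(n = 6)
  prior <- default_prior(m)
  J <- csd_parameter_jacobian(m, frequencies = f, prior = prior)
  expect_false("beta" %in% colnames(J))          # not tunable by default
  expect_true("alpha_meas" %in% colnames(J))

  # d/d alpha_meas of exp(alpha_meas) f^-beta on the diagonal is the term
  # itself: closed-form derivative of the additive measurement noise
  th <- pack_parameters(m)
  shape <- exp(th[["alpha_meas"]]) * as.numeric(f)^(-th[["beta"]])
  expected <- array(0, c(6, 2, 2))
  for (ch in 1:2) expected[, ch, ch] <- shape
  expect_equal(J[, "alpha_meas"], c(as.numeric(expected), rep(0, 24)),
               tolerance = 1e-6)

  pr2 <- set_tunable(prior, "alpha_meas", FALSE)
  J2 <- csd_parameter_jacobian(m, frequencies = f, prior = pr2)
  expect_false("alpha_meas" %in% colnames(J2))
  expect_equal(ncol(J2), ncol(J) - 1)
})

test_that("central differences shrink at second order (Richardson check)", {
  m <- assemble_circuit(matrix(0, 2, 2))
  f <- frequency_grid(n = 4)
  Jref <- csd_parameter_jacobian(m, frequencies = f, step = 1e-5)
  e1 <- max(abs(csd_parameter_jacobian(m, frequencies = f, step = 4e-2) - Jref))
  e2 <- max(abs(csd_parameter_jacobian(m, frequencies = f, step = 2e-2) - Jref))
  expect_gt(e1 / e2, 2.5)
  expect_lt(e1 / e2, 6)

  # a forward-difference backend satisfies the same contract more loosely
  Jf <- csd_parameter_jacobian(m, frequencies = f, step = 1e-5,
                               method = "forward")
  expect_equal(Jf, Jref, tolerance = 1e-3)
})

test_that("free energy has zero parameter KL at the prior and penalizes error", {
  set.seed(9)
  ne <- 20
  e <- rnorm(ne, sd = 0.1)
  J <- matrix(rnorm(ne * 2), ne, 2)
  prior <- gaussian_prior(c(p1 = 0.3, p2 = -0.1), c(0.5, 0.25))
  hyper <- spectraldcm:::resolve_hyper(hyperparameters(var = 0,
                                                       tunable = FALSE), ne)
  mu <- prior$mean
  Sq <- diag(prior$var)
  F0 <- free_energy(e, J, mu, Sq, prior, hyper, lambda = 0)
  Pi <- rep(1, ne)
  acc <- -0.5 * sum(Pi * e^2) - 0.5 * sum(rowSums((J %*% Sq) * J)) -
    0.5 * ne * log(2 * pi)
  expect_equal(F0, acc)                         # KL terms vanish exactly

  F2 <- free_energy(2 * e, J, mu, Sq, prior, hyper, lambda = 0)
  expect_lt(F2, F0)
})

test_that("the scheme reproduces the conjugate-Gaussian posterior exactly", {
  y <- 0.7; mp <- 0.2; vp <- 2; ve <- 0.5
  prior <- gaussian_prior(c(theta = mp), vp)
  hyper <- hyperparameters(mean = log(1 / ve), var = 0, tunable = FALSE)
  post <- vl_invert(y, function(th) th[["theta"]], prior, hyper)

  pm <- (y / ve + mp / vp) / (1 / ve + 1 / vp)
  pv <- 1 / (1 / ve + 1 / vp)
  lnZ <- stats::dnorm(y, mp, sqrt(vp + ve), log = TRUE)
  expect_equal(post$mean[["theta"]], pm, tolerance = 1e-6)
  expect_equal(post$cov[1, 1], pv, tolerance = 1e-6)
  expect_equal(post$F, lnZ, tolerance = 1e-4)
  expect_true(post$converged)

  # multivariate version with an informative map
  set.seed(21)
  A <- matrix(rnorm(12), 4, 3)
  theta0 <- c(a = 0.3, b = -0.2, c = 0.1)
  yv <- drop(A %*% theta0) + c(0.05, -0.02, 0.01, 0.03)
  pr <- gaussian_prior(c(a = 0, b = 0, c = 0), 1)
  hy <- hyperparameters(mean = log(1 / 0.01), var = 0, tunable = FALSE)
  post2 <- vl_invert(yv, function(th) drop(A %*% th), pr, hy)
  H <- t(A) %*% A / 0.01 + diag(3)
  mu_exact <- solve(H, t(A) %*% yv / 0.01)
  expect_equal(unname(post2$mean), drop(mu_exact), tolerance = 1e-6)
  expect_equal(unname(post2$cov), solve(H), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("update steps vanish under heavy damping and rejections change nothing", {
  y <- 0.7
  prior <- gaussian_prior(c(theta = 0.2), 2)
  hyper <- spectraldcm:::resolve_hyper(
    hyperparameters(mean = log(2), var = 0, tunable = FALSE), 1)
  predict <- function(th) th[["theta"]]
  J <- matrix(1, 1, 1, dimnames = list(NULL, "theta"))

  state <- list(mu = c(theta = 0.2), lambda = log(2),
                Sigma_q = matrix(0.4, 1, 1), F = -5,
                damping = 1e12, damping_floor = 1e-8)
  out <- vl_update_step(state, J, y, predict, prior, hyper)
  expect_lt(abs(out$mu[["theta"]] - 0.2), 1e-9)   # regularization limit

  # force a rejection by claiming a free energy no proposal can beat
  state$damping <- 1 / 32
  state$F <- 1e9
  out2 <- vl_update_step(state, J, y, predict, prior, hyper)
  expect_false(out2$accepted)
  expect_identical(out2$mu, state$mu)
  expect_identical(out2$lambda, state$lambda)
  expect_identical(out2$Sigma_q, state$Sigma_q)
  expect_equal(out2$damping, state$damping * 4)

  # the analytic posterior mean is a fixed point of accepted updates
  pm <- (2 * y + 0.5 * 0.2) / 2.5
  state3 <- list(mu = c(theta = pm), lambda = log(2),
                 Sigma_q = matrix(0.4, 1, 1), F = -1e9,
                 damping = 1e-4, damping_floor = 1e-8)
  out3 <- vl_update_step(state3, J, y, predict, prior, hyper)
  expect_equal(out3$mu[["theta"]], pm, tolerance = 1e-6)
})

test_that("noiseless self-consistency: data at the prior mean stay there", {
  m <- assemble_circuit(matrix(0, 2, 2))
  f <- frequency_grid(n = 12)
  S <- predict_csd(m, frequencies = f)
  post <- dcm_invert(S, m)
  pr <- default_prior(m)
  tn <- post$tunable
  expect_equal(post$mean[tn], pr$mean[tn], tolerance = 1e-8)
  # residuals are (numerically) zero, so the estimated log-precision is
  # driven to its ceiling
  expect_gt(post$lambda, 20)
})

test_that("free energy is non-decreasing over accepted iterations", {
  post <- recovery_fit(1)
  acc <- post$trace[which(post$trace$accepted %in% TRUE), ]
  expect_gt(nrow(acc), 2)
  expect_true(all(diff(post$trace$F) >= 0))
  expect_true(all(acc$dF > 0))
  # posterior covariance is symmetric positive definite
  expect_equal(post$cov, t(post$cov), tolerance = 1e-10)
  expect_gt(min(eigen(post$cov, only.values = TRUE)$values), 0)
})

test_that("posterior reports serialize and reload faithfully", {
  post <- recovery_fit(1)
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior(post, path)
  back <- read_posterior(path)
  expect_equal(back$mean, post$mean)
  expect_equal(back$F, post$F)
  expect_equal(back$data_hash, post$data_hash)
  expect_equal(unname(back$cov), unname(post$cov), tolerance = 1e-12)
})
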