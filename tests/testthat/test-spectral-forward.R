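# Linearization, transfer functions and predicted cross-spectral densities.

test_that("linearize returns A exactly for a purely linear system", {
  ou <- ou_model(0.7)
  lin <- linearize(ou)
  expect_equal(lin$J, matrix(-0.7, 1, 1))
  expect_equal(lin$G, matrix(1, 1, 1))
})

test_that("the default three-region model is stable at its prior means", {
  m <- assemble_circuit(matrix(0, 3, 3))
  lin <- linearize(m)
  expect_true(all(Re(lin$eig) < 0))
})

test_that("unstable models raise an informative error", {
  m <- assemble_circuit(matrix(0, 2, 2))
  th <- pack_parameters(m)
  th[c("a_1_2", "a_2_1")] <- c(2, 2)   # coupling overwhelms self-inhibition
  expect_error(linearize(m, th), "unstable")
  expect_error(predict_csd(m, th, frequency_grid(n = 4)), "unstable")
})

test_that("expansion-point perturbation at 1e-10 barely moves the Jacobian", {
  m <- assemble_circuit(matrix(0, 3, 3))
  J0 <- linearize(m)$J
  set.seed(1)
  J1 <- linearize(m, perturb = 1e-10)$J
  nz <- abs(J0) > 1e-12
  expect_lt(max(abs((J1[nz] - J0[nz]) / J0[nz])), 1e-6)
  expect_false(identical(J0, J1))
})

test_that("scalar transfer function matches its closed form", {
  l0 <- 0.4
  f <- frequency_grid(0.001, 0.5, 16)
  K <- transfer_function(linearize(ou_model(l0)), f)
  expect_equal(K[, 1, 1], 1 / (l0 + 2i * pi * as.numeric(f)),
               tolerance = 1e-12)
  # low-frequency limit 1/l0 and resolvent decay at high frequency
  expect_equal(Mod(K[1, 1, 1]), 1 / l0, tolerance = 1e-2)
  Khi <- transfer_function(linearize(ou_model(l0)), 1e5)
  expect_lt(Mod(Khi[1, 1, 1]), 1e-4)
})

test_that("matrix transfer function equals Fourier quadrature of the kernel", {
  skip_if_not_installed("Matrix")
  m <- assemble_circuit(matrix(c(0, 0.3, -0.2, 0), 2, 2))
  lin <- linearize(m)
  f <- c(0.01, 0.05, 0.25)
  K <- transfer_function(lin, f)

  # Simpson quadrature of G exp(J tau) B e^{-2 pi i f tau} over [0, T];
  # T chosen so exp(max Re eig * T) < 1e-9
  T_end <- 80; dtau <- 0.005; n <- round(T_end / dtau)
  E <- as.matrix(Matrix::expm(lin$J * dtau))
  M <- diag(nrow(lin$J))
  GB <- array(0, c(n + 1, 2, 2))
  for (k in 0:n) {
    GB[k + 1, , ] <- lin$G %*% M %*% lin$B
    M <- M %*% E
  }
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1) * dtau / 3
  tau <- (0:n) * dtau
  for (j in seq_along(f)) {
    ph <- exp(-2i * pi * f[j] * tau)
    Kq <- matrix(0 + 0i, 2, 2)
    for (a in 1:2) for (b in 1:2) Kq[a, b] <- sum(w * ph * GB[, a, b])
    expect_lt(max(Mod(K[j, , ] - Kq)) / max(Mod(K[j, , ])), 1e-6)
  }
})

test_that("noise spectra have the prescribed power-law structure", {
  f <- frequency_grid(0.01, 0.25, 8)
  p_flat <- noise_spectra_params(log(2), log(c(1, 3, 5)), log(0.7), beta = 0)
  ns <- noise_csd(p_flat, f, 3)
  expect_true(all(apply(ns$Sf, 2, function(x) diff(range(x))) == 0))
  expect_true(all(apply(ns$Sg, 2, function(x) diff(range(x))) == 0))
  # distinct region amplitudes, identical measurement diagonal
  expect_equal(ns$Sf[1, ], 2 + c(1, 3, 5))
  expect_equal(ns$Sg[1, ], rep(0.7, 3))

  p1 <- noise_spectra_params(log(1), log(1), log(1), beta = 1)
  p2 <- noise_spectra_params(log(2), log(1), log(1), beta = 1)
  n1 <- noise_csd(p1, f, 3); n2 <- noise_csd(p2, f, 3)
  expect_true(all(n2$Sf > n1$Sf))
  expect_equal(n1$Sf[, 1], as.numeric(f)^-1 * 2)
})

test_that("predicted CSD of the OU process is the Lorentzian closed form", {
  l0 <- 0.4
  f <- frequency_grid(1 / 128, 0.25, 32)
  S <- predict_csd(ou_model(l0), frequencies = f)
  lor <- 1 / (l0^2 + (2 * pi * as.numeric(f))^2)
  expect_lt(max(abs(Re(S$values[, 1, 1]) - lor) / lor), 1e-8)
  expect_equal(max(abs(Im(S$values))), 0)
})

test_that("with state noise silenced the predicted CSD is the measurement floor", {
  m <- assemble_circuit(matrix(0, 2, 2))
  th <- pack_parameters(m)
  th[c("alpha_global", "alpha_region_1", "alpha_region_2")] <- -60
  f <- frequency_grid(n = 8)
  S <- predict_csd(m, th, f)
  Sg <- exp(th[["alpha_meas"]]) * as.numeric(f)^(-th[["beta"]])
  for (k in 1:8) {
    expect_equal(S$values[k, , ], diag(Sg[k], 2) + 0i, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("predicted CSDs are Hermitian and PSD for random stable circuits", {
  set.seed(202)
  f <- frequency_grid(n = 8)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    A <- matrix(rnorm(n * n, sd = 0.15), n, n)
    diag(A) <- 0
    m <- assemble_circuit(A)
    th <- pack_parameters(m)
    th[sprintf("transit_%d", 1:n)] <- rnorm(n, sd = 0.2)
    th[["alpha_meas"]] <- rnorm(1, log(1e-6), 0.5)
    S <- tryCatch(predict_csd(m, th, f), error = function(e) NULL)
    if (is.null(S)) next                 # unstable draw: rejected upstream
    expect_hermitian_psd(S)
  }
})

test_that("CSD serialization round-trips", {
  m <- assemble_circuit(matrix(0, 2, 2), labels = c("PCC", "mPFC"))
  S <- predict_csd(m, frequencies = frequency_grid(n = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_csd(S, path)
  S2 <- read_csd(path)
  expect_equal(S2$values, S$values)
  expect_equal(S2$labels, S$labels)
  expect_equal(as.numeric(S2$frequencies), as.numeric(S$frequencies))
})
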