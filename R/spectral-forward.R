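# Linearization at the resting fixed point and prediction of the
# cross-spectral density of the observations.
#
# All public interfaces use frequency f in Hz; angular-frequency factors of
# 2*pi are internal.  Spectral convention throughout the package: one-sided
# spectral density per Hz, so that the integral of the diagonal over
# (0, Nyquist] equals the process variance.

#' Frequency grid
#'
#' Strictly increasing vector of positive frequencies (Hz).  The fMRI
#' default covers the resting-state band with 32 linearly spaced bins on
#' `[1/128, 0.25]` Hz; when `nyquist` is supplied (e.g. `1/(2 TR)` of the
#' data) the grid is truncated there.
#'
#' @param from,to Band edges in Hz.
#' @param n Number of bins.
#' @param nyquist Optional Nyquist frequency of the target data.
#' @return Numeric vector of class `frequency_grid`.
#' @export
frequency_grid <- function(from = 1 / 128, to = 0.25, n = 32, nyquist = NULL) {
  stopifnot(from > 0, to > from, n >= 2)
  if (!is.null(nyquist)) to <- min(to, nyquist)
  if (to <= from) stop("truncated band is empty; lower `from` or raise `nyquist`")
  f <- seq(from, to, length.out = n)
  structure(f, class = c("frequency_grid", "numeric"))
}

check_grid <- function(f) {
  f <- as.numeric(f)
  if (length(f) < 1 || any(f <= 0) || is.unsorted(f, strictly = TRUE)) {
    stop("frequency grid must be strictly positive and strictly increasing")
  }
  f
}

#' Cross-spectral density container
#'
#' @param values Complex array `(n_freq, n_channels, n_channels)`, Hermitian
#'   at every frequency.
#' @param frequencies Frequency grid (Hz).
#' @param labels Channel labels.
#' @return Object of class `dcm_csd`.
#' @export
new_csd <- function(values, frequencies, labels = NULL) {
  frequencies <- check_grid(frequencies)
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(frequencies),
            dim(values)[2] == dim(values)[3])
  nc <- dim(values)[2]
  if (is.null(labels)) labels <- paste0("ch", seq_len(nc))
  stopifnot(length(labels) == nc)
  dimnames(values) <- list(NULL, labels, labels)
  structure(list(values = values, frequencies = frequencies, labels = labels),
            class = "dcm_csd")
}

#' @export
print.dcm_csd <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<dcm_csd> %d channel(s) [%s] x %d frequencies (%.4g-%.4g Hz)\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              length(f), min(f), max(f)))
  invisible(x)
}

#' Linearize a composed model at its expansion point
#'
#' Evaluates the state Jacobian `J` and observation gradient `G` of the
#' model at the resting fixed point (the zero vector in the transformed
#' coordinates), verifies Hurwitz stability, and returns them with the
#' state-noise input map `B`.  An optional i.i.d. Gaussian perturbation of
#' the expansion point (scale `perturb`, e.g. `1e-10`) is available as a
#' robustness device for differentiation schemes that are unstable at
#' degenerate (repeated) eigenvalues.
#'
#' @param model A `dcm_model`.
#' @param theta Parameter vector (default: packed model defaults).
#' @param perturb Standard deviation of the expansion-point perturbation
#'   (0 = exact fixed point).
#' @param fd_step Step for the finite-difference fallback Jacobian.
#' @return List of class `dcm_linsys` with elements `J`, `G`, `B` and the
#'   eigenvalues `eig` of `J`.
#' @export
linearize <- function(model, theta = pack_parameters(model), perturb = 0,
                      fd_step = 1e-6) {
  stopifnot(inherits(model, "dcm_model"))
  theta <- check_theta(model, theta)
  x0 <- numeric(model$n_states)
  if (perturb > 0) x0 <- x0 + stats::rnorm(model$n_states, sd = perturb)
  J <- if (is.function(model$jacobian)) {
    model$jacobian(x0, theta)
  } else {
    fd_jacobian(function(x) model$flow(x, theta), x0, fd_step)
  }
  G <- if (is.function(model$obs_grad)) {
    model$obs_grad(x0, theta)
  } else {
    fd_jacobian(function(x) model$obs(x, theta), x0, fd_step,
                n_out = model$n_channels)
  }
  G <- matrix(G, nrow = model$n_channels)
  ev <- eigen(J, only.values = TRUE)$values
  worst <- max(Re(ev))
  if (worst >= 0) {
    k <- which.max(Re(ev))
    stop(sprintf(
      "unstable model: eigenvalue %d of the Jacobian has Re = %.3g >= 0 (%s)",
      k, worst, format(ev[k], digits = 4)), call. = FALSE)
  }
  structure(list(J = J, G = G, B = model$B, eig = ev), class = "dcm_linsys")
}

# central finite-difference Jacobian of f at x
fd_jacobian <- function(f, x, h = 1e-6, n_out = NULL) {
  f0 <- f(x)
  if (is.null(n_out)) n_out <- length(f0)
  J <- matrix(0, n_out, length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Transfer function of the linearized system
#'
#' Resolvent form of the Fourier-transformed convolution kernel:
#' `K(f) = G (2 pi i f I - J)^-1 B`, the frequency response from the
#' state-noise inputs to the observed channels.
#'
#' @param lin A `dcm_linsys` from [linearize()].
#' @param frequencies Frequency grid (Hz).
#' @return Complex array `(n_freq, n_channels, n_regions)`.
#' @export
transfer_function <- function(lin, frequencies) {
  stopifnot(inherits(lin, "dcm_linsys"))
  f <- check_grid(frequencies)
  ns <- nrow(lin$J)
  nc <- nrow(lin$G); nr <- ncol(lin$B)
  K <- array(0 + 0i, c(length(f), nc, nr))
  I <- diag(ns)
  for (k in seq_along(f)) {
    R <- tryCatch(solve((2i * pi * f[k]) * I - lin$J, lin$B),
                  error = function(e) {
                    stop(sprintf("singular resolvent at f = %.4g Hz", f[k]),
                         call. = FALSE)
                  })
    K[k, , ] <- lin$G %*% R
  }
  K
}

#' Power-law noise cross-spectra
#'
#' One-sided diagonal spectral densities of the endogenous state noise and
#' the measurement noise on a frequency grid.  State-noise diagonal for
#' region r: `(exp(alpha_global) + exp(alpha_region[r])) * f^-beta`;
#' measurement diagonal, identical across channels:
#' `exp(alpha_meas) * f^-beta`.  Off-diagonals are zero (uncorrelated
#' noise).
#'
#' @param p [noise_spectra_params()].
#' @param frequencies Frequency grid (Hz).
#' @param n_regions,n_channels Numbers of noise inputs / channels.
#' @return List with matrices `Sf` (`n_freq x n_regions`) and `Sg`
#'   (`n_freq x n_channels`) holding the diagonals.
#' @export
noise_csd <- function(p, frequencies, n_regions, n_channels = n_regions) {
  stopifnot(inherits(p, "noise_spectra_params"))
  f <- check_grid(frequencies)
  shape <- f^(-p$beta)
  amp <- exp(p$alpha_global) + exp(rep_len(p$alpha_region, n_regions))
  list(Sf = outer(shape, amp),
       Sg = matrix(exp(p$alpha_meas) * shape, length(f), n_channels))
}

#' Predict the cross-spectral density of the observations
#'
#' Spectral forward model: with `K(f)` the transfer function of the
#' linearized system and `S_ef`, `S_eg` the diagonal state- and
#' measurement-noise spectra,
#' `S_y(f) = K(f) S_ef(f) K(f)^H + S_eg(f)`.
#' The result is Hermitian and positive semidefinite at every frequency.
#'
#' @param model A `dcm_model`.
#' @param theta Parameter vector (default: model defaults).
#' @param frequencies Frequency grid (Hz).
#' @param perturb Optional expansion-point perturbation scale, see
#'   [linearize()].
#' @return A `dcm_csd`.
#' @export
predict_csd <- function(model, theta = pack_parameters(model),
                        frequencies = frequency_grid(), perturb = 0) {
  stopifnot(inherits(model, "dcm_model"))
  theta <- check_theta(model, theta)
  f <- check_grid(frequencies)
  lin <- linearize(model, theta, perturb = perturb)
  K <- transfer_function(lin, f)
  NS <- model$noise_spectra(theta, f)
  nc <- model$n_channels
  S <- array(0 + 0i, c(length(f), nc, nc))
  for (k in seq_along(f)) {
    Kk <- matrix(K[k, , ], nrow = nc)
    S[k, , ] <- Kk %*% (NS$Sf[k, ] * Conj(t(Kk))) + diag(NS$Sg[k, ], nc)
  }
  new_csd(S, f, model$labels)
}

#' Serialize a cross-spectral density to JSON
#'
#' Stores frequencies, channel labels and the real/imaginary parts of the
#' spectral array in a plain-text JSON document readable by [read_csd()].
#'
#' @param csd A `dcm_csd`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csd <- function(csd, path) {
  stopifnot(inherits(csd, "dcm_csd"))
  obj <- list(schema_version = "1.0",
              frequencies = as.numeric(csd$frequencies),
              labels = csd$labels,
              dim = dim(csd$values),
              re = as.numeric(Re(csd$values)),
              im = as.numeric(Im(csd$values)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cross-spectral density written by [write_csd()]
#'
#' @param path JSON file path.
#' @return A `dcm_csd`.
#' @export
read_csd <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  values <- array(complex(real = obj$re, imaginary = obj$im), obj$dim)
  new_csd(values, obj$frequencies, obj$labels)
}
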