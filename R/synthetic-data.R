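# Seeded generation of synthetic BOLD time series from the full nonlinear
# generative model: power-law noise synthesis, Euler-Maruyama integration
# and the default three-region recovery scenario.

# run expr with a local RNG stream seeded by `seed`, restoring the global
# state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# one column of stationary noise whose one-sided spectral density is S(f_k)
# on the FFT grid, by spectral synthesis (scale white-noise Fourier
# coefficients by sqrt(S), inverse transform)
power_law_series <- function(n, dt, spectrum) {
  f <- seq_len(n - 1) / (n * dt)              # positive FFT frequencies
  half <- floor((n - 1) / 2)
  S <- spectrum(f[seq_len(half)])
  X <- complex(real = numeric(n), imaginary = numeric(n))
  amp <- sqrt(S * n / (2 * dt))
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) /
    sqrt(2)
  X[2:(half + 1)] <- amp * z
  X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
  if (n %% 2 == 0) {                          # real Nyquist coefficient
    fn <- 1 / (2 * dt)
    X[n / 2 + 1] <- sqrt(spectrum(fn) * n / (2 * dt)) * stats::rnorm(1)
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Sample colored (power-law) noise
#'
#' Generates stationary real-valued series whose one-sided spectral density
#' follows the power law of [noise_spectra_params()]:
#' `component = "state"` draws one series per region with density
#' `(exp(alpha_global) + exp(alpha_region[r])) f^-beta`;
#' `component = "measurement"` draws `n_series` channels with density
#' `exp(alpha_meas) f^-beta`.  For exponents `beta > 0` the density is
#' capped below `f_floor` (default `1/(n dt)`, the fundamental of the
#' record) so that the synthesis stays finite.
#'
#' @param p A [noise_spectra_params()].
#' @param n Number of samples (powers of two are fastest but any length
#'   works).
#' @param dt Sampling interval (s).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param component `"state"` or `"measurement"`.
#' @param n_series Number of series (regions/channels).
#' @param f_floor Low-frequency cap (Hz).
#' @return Matrix `(n x n_series)`.
#' @export
sample_colored_noise <- function(p, n, dt, seed,
                                 component = c("state", "measurement"),
                                 n_series = NULL, f_floor = NULL) {
  stopifnot(inherits(p, "noise_spectra_params"), n > 8, dt > 0)
  component <- match.arg(component)
  if (is.null(f_floor)) f_floor <- 1 / (n * dt)
  amp <- if (component == "state") {
    nr <- if (is.null(n_series)) length(p$alpha_region) else n_series
    exp(p$alpha_global) + exp(rep_len(p$alpha_region, nr))
  } else {
    nr <- if (is.null(n_series)) 1L else n_series
    rep(exp(p$alpha_meas), nr)
  }
  with_seed(seed, {
    out <- matrix(0, n, length(amp))
    for (j in seq_along(amp)) {
      spec <- function(f) amp[j] * pmax(f, f_floor)^(-p$beta)
      out[, j] <- power_law_series(n, dt, spec)
    }
    out
  })
}

#' Simulate BOLD time series from the full nonlinear model
#'
#' Euler-Maruyama integration of the composed neuronal + hemodynamic system
#' driven by sampled power-law state noise, observation through the BOLD
#' equation plus sampled measurement noise, decimation to the repetition
#' time and removal of the initial transient.
#'
#' @param model A `dcm_model` (stable at `theta`).
#' @param theta Generative parameter vector.
#' @param duration Total simulated time (s), including the transient.
#' @param dt Integration step (s); default 0.1.
#' @param TR Repetition time (s); must be a multiple of `dt`.
#' @param seed Integer seed.
#' @param transient Initial stretch discarded (s); default 32.
#' @return Matrix `(n_vol x n_regions)` of observed signals with attributes
#'   `TR` and column names from the model labels, where
#'   `n_vol = floor((duration - transient)/TR)`.
#' @export
simulate_bold <- function(model, theta = pack_parameters(model),
                          duration = 1056, dt = 0.1, TR = 2, seed = 1,
                          transient = 32) {
  stopifnot(inherits(model, "dcm_model"), duration > transient + TR)
  theta <- check_theta(model, theta)
  if (abs(TR / dt - round(TR / dt)) > 1e-9) {
    stop("TR must be a multiple of the integration step dt")
  }
  linearize(model, theta)   # errors before integration if unstable
  np <- resolve_model_noise(model, theta)
  n_steps <- round(duration / dt)
  eps <- sample_colored_noise(np, n_steps, dt, seed, "state",
                              n_series = model$n_regions)
  stride <- round(TR / dt)
  keep <- seq(round(transient / dt) + stride, n_steps, by = stride)
  n_vol <- floor((duration - transient) / TR)
  keep <- keep[seq_len(min(n_vol, length(keep)))]

  x <- numeric(model$n_states)
  Y <- matrix(0, length(keep), model$n_channels)
  row <- 1L
  for (t in seq_len(n_steps)) {
    x <- x + dt * (model$flow(x, theta) + drop(model$B %*% eps[t, ]))
    if (row <= length(keep) && t == keep[row]) {
      Y[row, ] <- model$obs(x, theta)
      row <- row + 1L
    }
  }
  noise <- sample_colored_noise(np, length(keep), TR, seed + 1L,
                                "measurement", n_series = model$n_channels)
  Y <- Y + noise
  colnames(Y) <- model$labels
  attr(Y, "TR") <- TR
  Y
}

# noise_spectra_params view of a model's parameter vector
resolve_model_noise <- function(model, theta) {
  if (identical(model$structure, "fmri")) {
    p <- fmri_pars(theta, model$n_regions)
    noise_spectra_params(p$alpha_global, p$alpha_region, p$alpha_meas,
                         p$beta)
  } else if (!is.null(model$noise_params)) {
    model$noise_params(theta)
  } else {
    stop("model does not define noise parameters for simulation")
  }
}

#' Default three-region recovery scenario
#'
#' The package's reference simulate-then-invert setting: a three-region
#' linear neural mass with generative off-diagonal connections
#' `a12 = -0.2`, `a21 = 0.4`, `a32 = -0.3`, `a23 = 0.2` (and
#' `a13 = a31 = 0`), balloon/BOLD observation, power-law endogenous and
#' measurement noise, sampled at TR = 2 s for 512 volumes after the
#' transient.  Priors are zero-mean with variance 1/128 on all connection
#' parameters.  The model and priors are identical across seeds; only the
#' noise realization changes.
#'
#' @param seed Integer seed for the data realization.
#' @param n_vol Number of retained volumes (default 512).
#' @return List with elements `model`, `theta_true`, `prior`, `data`
#'   (matrix with `TR` attribute), `TR` and `seed`.
#' @export
default_scenario <- function(seed = 1, n_vol = 512) {
  TR <- 2; transient <- 32
  A_true <- matrix(0, 3, 3)
  A_true[2, 1] <- -0.2    # a12: region 1 onto region 2
  A_true[1, 2] <- 0.4     # a21
  A_true[2, 3] <- -0.3    # a32
  A_true[3, 2] <- 0.2     # a23
  model <- assemble_circuit(matrix(0, 3, 3))
  theta_true <- pack_parameters(model)
  for (from in 1:3) {
    for (to in 1:3) {
      if (from != to) {
        theta_true[[connection_name(from, to)]] <- A_true[to, from]
      }
    }
  }
  prior <- default_prior(model)
  data <- simulate_bold(model, theta_true,
                        duration = transient + n_vol * TR, dt = 0.1,
                        TR = TR, seed = seed, transient = transient)
  list(model = model, theta_true = theta_true, prior = prior, data = data,
       TR = TR, seed = seed)
}

#' Write a scenario's metadata for recovery scoring
#'
#' Stores the generative parameters and seed as JSON next to the simulated
#' series so that recovery errors can be scored later.
#'
#' @param scenario A list from [default_scenario()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scenario_meta <- function(scenario, path) {
  obj <- list(schema_version = "1.0",
              seed = scenario$seed, TR = scenario$TR,
              theta_true = as.list(scenario$theta_true))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
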