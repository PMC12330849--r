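# Region-level neuronal dynamics, circuit assembly and the flat parameter
# vector exposed to inference.
#
# State layout of the composed fMRI model: per region
#   [x, s, lu, lv, lq]
# where x is neuronal activity, s the vasodilatory signal, and lu, lv, lq the
# logarithms of blood flow u, volume v and deoxyhemoglobin q.  Propagating
# u, v, q in log space makes positivity structural and places the resting
# steady state at the zero vector, which is the expansion point of the
# spectral forward model.

#' Effective connectivity matrix
#'
#' Validates a square matrix of directed connection rates.  Convention:
#' element `(y, x)` holds `a_xy`, the influence exerted by region `x` onto
#' region `y` (row = target, column = source), so the neuronal flow is
#' `dx/dt = A x`.
#'
#' @param A Square numeric matrix of rates (Hz).
#' @return The validated matrix.
#' @export
effective_connectivity <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("connectivity matrix must be square")
  if (!is.numeric(A) || anyNA(A)) stop("connectivity matrix must be numeric and finite")
  A
}

#' Linear neural-mass flow
#'
#' Derivative of the neuronal state under the linear neural-mass model,
#' `dx/dt = A x`, with the (target-row, source-column) convention of
#' [effective_connectivity()].
#'
#' @param A Effective connectivity matrix (n x n, Hz).
#' @param x Neuronal state vector (length n).
#' @return Derivative vector (Hz).
#' @export
linear_flow <- function(A, x) {
  A <- effective_connectivity(A)
  if (length(x) != nrow(A)) {
    stop(sprintf("state has length %d but connectivity is %d x %d",
                 length(x), nrow(A), ncol(A)))
  }
  drop(A %*% x)
}

#' Power-law noise spectrum parameters
#'
#' Log-amplitudes and spectral exponent of the endogenous (state) and
#' measurement noise.  The one-sided spectral density of the state noise
#' entering region r is `(exp(alpha_global) + exp(alpha_region[r])) * f^-beta`
#' and that of the measurement noise on every channel is
#' `exp(alpha_meas) * f^-beta` (uncorrelated noise: both spectra are diagonal;
#' the measurement diagonal is shared across channels while state-noise
#' diagonals may differ through the region-specific component).
#'
#' Default amplitudes are chosen so that, for the three-region demonstration
#' circuit, simulated BOLD fluctuations have a standard deviation of roughly
#' 0.1-1 percent signal change with in-band measurement noise well below the
#' signal (see the methods vignette).
#'
#' @param alpha_global Log-amplitude of the global state-noise component.
#' @param alpha_region Per-region log-amplitudes (recycled to `n_regions` by
#'   consumers when scalar).
#' @param alpha_meas Log-amplitude of measurement noise (shared across
#'   channels).
#' @param beta Spectral exponent (applied to frequency in Hz).
#' @return An object of class `noise_spectra_params`.
#' @export
noise_spectra_params <- function(alpha_global = log(3e-6),
                                 alpha_region = log(3e-6),
                                 alpha_meas = log(1e-6),
                                 beta = 1) {
  stopifnot(is.finite(alpha_global), all(is.finite(alpha_region)),
            is.finite(alpha_meas), is.finite(beta))
  structure(list(alpha_global = alpha_global, alpha_region = alpha_region,
                 alpha_meas = alpha_meas, beta = beta),
            class = "noise_spectra_params")
}

state_names <- function(labels) {
  as.vector(vapply(labels, function(l) {
    paste(c("x", "s", "lu", "lv", "lq"), l, sep = ".")
  }, character(5)))
}

#' Low-level model constructor
#'
#' Builds a composed generative model from programmatic callables.  Most
#' users should call [assemble_circuit()]; this constructor exists so that
#' arbitrary dynamics (e.g. a scalar Ornstein-Uhlenbeck process in tests, or
#' other neural-mass families) can be wrapped in the same interface and run
#' through [predict_csd()] and [dcm_invert()].
#'
#' All models must use coordinates in which the expansion point (fixed point
#' of `flow` at the default parameters) is the zero state vector.
#'
#' @param flow `function(x, theta)` returning the full state derivative.
#' @param obs `function(x, theta)` returning the observed channels.
#' @param params Data frame with columns `name`, `value` (default/prior
#'   mean), `tunable` (logical) and `prior_var` (prior variance).
#' @param n_states,n_regions,n_channels Dimensions.
#' @param labels Character vector of region labels (length `n_regions`).
#' @param B State-noise input map (`n_states x n_regions`) routing endogenous
#'   noise into the state equations.
#' @param noise_spectra `function(theta, f)` returning
#'   `list(Sf = n_f x n_regions, Sg = n_f x n_channels)` one-sided noise
#'   spectral densities.
#' @param jacobian Optional `function(x, theta)` returning the analytic
#'   state Jacobian; when `NULL` central finite differences are used.
#' @param obs_grad Optional analytic observation gradient
#'   `function(x, theta)` (`n_channels x n_states`).
#' @param structure Parameter-vector structure tag (`"flat"` for generic
#'   models, `"fmri"` for circuits built by [assemble_circuit()]).
#' @param extra Named list of additional fields stored on the model.
#' @return An object of class `dcm_model`.
#' @export
new_dcm_model <- function(flow, obs, params, n_states, n_regions, n_channels,
                          labels = paste0("R", seq_len(n_regions)),
                          B = NULL, noise_spectra = NULL,
                          jacobian = NULL, obs_grad = NULL,
                          structure = "flat", extra = list()) {
  stopifnot(is.function(flow), is.function(obs), is.data.frame(params))
  need <- c("name", "value", "tunable", "prior_var")
  if (!all(need %in% names(params))) {
    stop("`params` must have columns name, value, tunable, prior_var")
  }
  if (anyDuplicated(params$name)) stop("parameter names must be unique")
  if (anyDuplicated(labels)) stop("duplicate region labels")
  if (length(labels) != n_regions) stop("labels must match n_regions")
  if (is.null(B)) {
    B <- matrix(0, n_states, n_regions)
    B[cbind(seq_len(n_regions), seq_len(n_regions))] <- 1
  }
  stopifnot(nrow(B) == n_states, ncol(B) == n_regions)
  m <- structure(c(list(flow = flow, obs = obs, params = params,
                        n_states = n_states, n_regions = n_regions,
                        n_channels = n_channels, labels = labels, B = B,
                        noise_spectra = noise_spectra, jacobian = jacobian,
                        obs_grad = obs_grad, structure = structure),
                   extra),
                 class = "dcm_model")
  m
}

#' Name of a directed connection parameter
#'
#' @param from Source region index.
#' @param to Target region index.
#' @return Parameter name string, e.g. `connection_name(1, 2)` is `"a_1_2"`,
#'   the influence of region 1 onto region 2 (stored at matrix element
#'   `(2, 1)`).
#' @export
connection_name <- function(from, to) sprintf("a_%d_%d", from, to)

fmri_param_table <- function(n, noise) {
  nm <- character(0); val <- numeric(0); tun <- logical(0); pv <- numeric(0)
  for (from in seq_len(n)) {
    for (to in seq_len(n)) {
      nm <- c(nm, connection_name(from, to))
      val <- c(val, 0)
      tun <- c(tun, TRUE)
      pv <- c(pv, 1 / 128)
    }
  }
  ar <- rep_len(noise$alpha_region, n)
  nm <- c(nm, sprintf("transit_%d", seq_len(n)), "alpha_global",
          sprintf("alpha_region_%d", seq_len(n)), "alpha_meas", "beta")
  val <- c(val, rep(0, n), noise$alpha_global, ar, noise$alpha_meas,
           noise$beta)
  tun <- c(tun, rep(TRUE, n), TRUE, rep(TRUE, n), TRUE, FALSE)
  pv <- c(pv, rep(1 / 256, n), 1 / 64, rep(1 / 64, n), 1 / 64, 1 / 64)
  data.frame(name = nm, value = val, tunable = tun, prior_var = pv,
             stringsAsFactors = FALSE)
}

#' Assemble regions into a composed generative model
#'
#' Composes `n` linear neural-mass regions, balloon-model hemodynamics and
#' the BOLD observation into one state-space model with 5 states per region.
#' Neuronal activity of region i drives region i's vasodilatory signal;
#' regions interact only through the effective-connectivity matrix.
#'
#' Parameterization of the flat vector theta (see [pack_parameters()]):
#' * `a_x_y` for x != y: off-diagonal connection rate (Hz), the influence of
#'   region x onto region y, stored at matrix element (y, x).
#' * `a_i_i`: self-connection parameter; the diagonal rate is
#'   `-0.5 * exp(a_i_i)` Hz so stability is favored at the prior mean 0.
#' * `transit_r`: log scale factor of region r's transit time,
#'   `tau_r = tau * exp(transit_r)`.
#' * `alpha_global`, `alpha_region_r`, `alpha_meas`, `beta`: power-law noise
#'   spectrum parameters ([noise_spectra_params()]); `beta` is not tunable
#'   by default.
#'
#' The observation is reported as percent signal change
#' (`100 * lambda(q, v)` with [bold_signal()]), the convention in which
#' resting-state BOLD fluctuations have amplitudes of order 0.1-1.
#'
#' @param connectivity Square matrix of prior-mean connection parameters
#'   (off-diagonal entries in Hz; diagonal entries on the log scale of the
#'   self-connection parameterization, usually 0).
#' @param labels Optional region labels (default `R1`, `R2`, ...).
#' @param hemo [hemodynamic_params()] shared across regions.
#' @param bold [bold_params()] shared across regions.
#' @param noise [noise_spectra_params()] supplying the default noise
#'   parameter values.
#' @param signal_scale Output scale of the observation; 100 reports percent
#'   signal change.
#' @return A `dcm_model` (see [new_dcm_model()]).
#' @export
assemble_circuit <- function(connectivity, labels = NULL,
                             hemo = hemodynamic_params(),
                             bold = bold_params(),
                             noise = noise_spectra_params(),
                             signal_scale = 100) {
  A0 <- effective_connectivity(connectivity)
  n <- nrow(A0)
  if (n < 1) stop("need at least one region")
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate region labels")
  if (length(labels) != n) stop("labels must match connectivity size")
  params <- fmri_param_table(n, noise)
  # prior means of connections come from the supplied matrix
  for (from in seq_len(n)) {
    for (to in seq_len(n)) {
      params$value[params$name == connection_name(from, to)] <- A0[to, from]
    }
  }
  k <- bold_coefficients(bold)
  nidx <- seq(1, by = 5, length.out = n)

  model <- new_dcm_model(
    flow = function(x, theta) fmri_flow(x, theta, n, hemo),
    obs = function(x, theta) fmri_obs(x, n, bold, k, signal_scale),
    params = params,
    n_states = 5 * n, n_regions = n, n_channels = n, labels = labels,
    B = {
      B <- matrix(0, 5 * n, n)
      B[cbind(nidx, seq_len(n))] <- 1
      B
    },
    noise_spectra = function(theta, f) fmri_noise_spectra(theta, f, n),
    jacobian = function(x, theta) fmri_jacobian(x, theta, n, hemo),
    obs_grad = function(x, theta) fmri_obs_grad(x, n, bold, k, signal_scale),
    structure = "fmri",
    extra = list(hemo = hemo, bold = bold, signal_scale = signal_scale)
  )
  model
}

# structured view of the flat fMRI parameter vector
fmri_pars <- function(theta, n) {
  A <- matrix(0, n, n)
  for (from in seq_len(n)) {
    for (to in seq_len(n)) {
      A[to, from] <- theta[[connection_name(from, to)]]
    }
  }
  raw_diag <- diag(A)
  diag(A) <- -0.5 * exp(raw_diag)
  list(A = A, a_diag = raw_diag,
       transit = unname(theta[sprintf("transit_%d", seq_len(n))]),
       alpha_global = theta[["alpha_global"]],
       alpha_region = unname(theta[sprintf("alpha_region_%d", seq_len(n))]),
       alpha_meas = theta[["alpha_meas"]],
       beta = theta[["beta"]])
}

fmri_flow <- function(x, theta, n, hemo) {
  p <- fmri_pars(theta, n)
  i <- seq(1, by = 5, length.out = n)
  xn <- x[i]; s <- x[i + 1]; lu <- x[i + 2]; lv <- x[i + 3]; lq <- x[i + 4]
  u <- exp(lu); q <- exp(lq)
  tau <- hemo$tau * exp(p$transit)
  cc <- 1 / hemo$alpha
  vc1 <- exp(lv * (cc - 1))        # v^(1/alpha - 1)
  E <- 1 - (1 - hemo$E0)^(1 / u)
  d <- numeric(5 * n)
  d[i] <- drop(p$A %*% xn)
  d[i + 1] <- xn - hemo$kappa * s - hemo$gamma * (u - 1)
  d[i + 2] <- s / u
  d[i + 3] <- (u * exp(-lv) - vc1) / tau
  d[i + 4] <- (u * E / (hemo$E0 * q) - vc1) / tau
  d
}

fmri_obs <- function(x, n, bold, k, scale) {
  i <- seq(1, by = 5, length.out = n)
  v <- exp(x[i + 3]); q <- exp(x[i + 4])
  scale * bold$V0 *
    (k[["k1"]] * (1 - q) + k[["k2"]] * (1 - q / v) + k[["k3"]] * (1 - v))
}

# analytic state Jacobian of the composed log-space flow (chain rule on
# Eqs. of the balloon model); validated against finite differences in tests
fmri_jacobian <- function(x, theta, n, hemo) {
  p <- fmri_pars(theta, n)
  J <- matrix(0, 5 * n, 5 * n)
  i <- seq(1, by = 5, length.out = n)
  J[i, i] <- p$A
  E0 <- hemo$E0; cc <- 1 / hemo$alpha
  for (r in seq_len(n)) {
    o <- (r - 1) * 5
    s <- x[o + 2]; lu <- x[o + 3]; lv <- x[o + 4]; lq <- x[o + 5]
    u <- exp(lu); q <- exp(lq)
    tau <- hemo$tau * exp(p$transit[r])
    vc1 <- exp(lv * (cc - 1))
    ue <- exp(-lv) * u                       # u / v
    E <- 1 - (1 - E0)^(1 / u)
    # d/du [u E(u)]
    dUE <- 1 - (1 - E0)^(1 / u) + (1 - E0)^(1 / u) * log(1 - E0) / u
    J[o + 2, o + 1] <- 1
    J[o + 2, o + 2] <- -hemo$kappa
    J[o + 2, o + 3] <- -hemo$gamma * u
    J[o + 3, o + 2] <- 1 / u
    J[o + 3, o + 3] <- -s / u
    J[o + 4, o + 3] <- ue / tau
    J[o + 4, o + 4] <- (-ue - (cc - 1) * vc1) / tau
    J[o + 5, o + 3] <- dUE * u / (E0 * q * tau)
    J[o + 5, o + 4] <- -(cc - 1) * vc1 / tau
    J[o + 5, o + 5] <- -u * E / (E0 * q * tau)
  }
  J
}

fmri_obs_grad <- function(x, n, bold, k, scale) {
  G <- matrix(0, n, 5 * n)
  for (r in seq_len(n)) {
    o <- (r - 1) * 5
    v <- exp(x[o + 4]); q <- exp(x[o + 5])
    G[r, o + 4] <- scale * bold$V0 * (k[["k2"]] * q / v - k[["k3"]] * v)
    G[r, o + 5] <- scale * bold$V0 * (-k[["k1"]] * q - k[["k2"]] * q / v)
  }
  G
}

fmri_noise_spectra <- function(theta, f, n) {
  shape <- f^(-theta[["beta"]])
  amp_f <- exp(theta[["alpha_global"]]) +
    exp(unname(theta[sprintf("alpha_region_%d", seq_len(n))]))
  list(Sf = outer(shape, amp_f),
       Sg = matrix(exp(theta[["alpha_meas"]]) * shape, length(f), n))
}

#' Pack model parameters into a flat named vector
#'
#' The canonical ordering is the row order of `model$params` (stable and
#' documented there): connection parameters `a_x_y` in source-major order,
#' then per-region transit factors, then noise parameters.
#'
#' @param model A `dcm_model`.
#' @param assignment Optional structured assignment as returned by
#'   [unpack_parameters()] (or a named numeric vector); `NULL` packs the
#'   model's default values.
#' @return Named numeric vector theta.
#' @export
pack_parameters <- function(model, assignment = NULL) {
  stopifnot(inherits(model, "dcm_model"))
  theta <- stats::setNames(model$params$value, model$params$name)
  if (is.null(assignment)) return(theta)
  if (is.numeric(assignment) && !is.null(names(assignment))) {
    unknown <- setdiff(names(assignment), names(theta))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    theta[names(assignment)] <- assignment
    return(theta)
  }
  if (identical(model$structure, "fmri") && is.list(assignment)) {
    n <- model$n_regions
    A <- assignment$A
    for (from in seq_len(n)) {
      for (to in seq_len(n)) {
        if (to != from) theta[[connection_name(from, to)]] <- A[to, from]
      }
    }
    theta[sprintf("a_%d_%d", seq_len(n), seq_len(n))] <- assignment$a_diag
    theta[sprintf("transit_%d", seq_len(n))] <- assignment$transit
    theta[["alpha_global"]] <- assignment$alpha_global
    theta[sprintf("alpha_region_%d", seq_len(n))] <- assignment$alpha_region
    theta[["alpha_meas"]] <- assignment$alpha_meas
    theta[["beta"]] <- assignment$beta
    return(theta)
  }
  stop("`assignment` must be a named numeric vector or a structured list")
}

#' Unpack a flat parameter vector into a structured assignment
#'
#' For circuits built by [assemble_circuit()] the result is a list with the
#' effective connectivity matrix `A` (self-connections already mapped to
#' `-0.5 * exp(a_ii)`), the raw diagonal parameters `a_diag`, per-region
#' `transit` log-factors and the noise parameters.  For generic models the
#' named vector itself is returned.  `pack_parameters(model,
#' unpack_parameters(model, theta))` is the identity.
#'
#' @param model A `dcm_model`.
#' @param theta Named or ordered numeric vector of length `nrow(model$params)`.
#' @return Structured parameter assignment.
#' @export
unpack_parameters <- function(model, theta) {
  stopifnot(inherits(model, "dcm_model"))
  theta <- check_theta(model, theta)
  if (!identical(model$structure, "fmri")) return(theta)
  fmri_pars(theta, model$n_regions)
}

# coerce/validate a parameter vector against the model's table
check_theta <- function(model, theta) {
  nm <- model$params$name
  if (length(theta) != length(nm)) {
    stop(sprintf("parameter vector has length %d, expected %d",
                 length(theta), length(nm)))
  }
  if (is.null(names(theta))) {
    names(theta) <- nm
  } else {
    if (!setequal(names(theta), nm)) stop("parameter names do not match model")
    theta <- theta[nm]
  }
  theta
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("<dcm_model> %d region(s): %s\n", x$n_regions,
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  states: %d, channels: %d, parameters: %d (%d tunable)\n",
              x$n_states, x$n_channels, nrow(x$params),
              sum(x$params$tunable & x$params$prior_var > 0)))
  invisible(x)
}
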