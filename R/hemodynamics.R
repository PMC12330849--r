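# Balloon-model hemodynamics and the BOLD observation equation.

#' Hemodynamic (balloon model) parameters
#'
#' Container for the rate constants of the balloon model linking neuronal
#' activity to blood flow, volume and deoxyhemoglobin content.  Defaults are
#' the standard resting-state values used as prior means; region-specific
#' deviations of the transit time are expressed multiplicatively via fitted
#' log-scale parameters (see [assemble_circuit()]).
#'
#' @param kappa Vasodilatory signal decay rate (1/s).
#' @param gamma Autoregulatory flow feedback rate (1/s).
#' @param tau Mean venous transit time at rest (s).
#' @param alpha Grubb's vessel stiffness exponent (dimensionless, in (0,1)).
#' @param E0 Resting oxygen extraction fraction (dimensionless, in (0,1)).
#'
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                               alpha = 0.32, E0 = 0.4) {
  stopifnot(kappa > 0, gamma > 0, tau > 0,
            alpha > 0, alpha < 1, E0 > 0, E0 < 1)
  structure(list(kappa = kappa, gamma = gamma, tau = tau,
                 alpha = alpha, E0 = E0),
            class = "hemodynamic_params")
}

#' Field-strength presets for the BOLD coefficients
#'
#' Literature-derived values of the frequency offset `theta0`, intravascular
#' relaxation slope `r0` and intra/extravascular signal ratio `epsilon_ratio`
#' for common scanner field strengths.  These presets are placeholders in the
#' sense that published estimates vary between studies; every value can be
#' overridden in [bold_params()] or through the config file.
#'
#' @return Named list of numeric vectors with entries `theta0`, `r0`,
#'   `epsilon_ratio`, keyed by field-strength label.
#' @export
field_strength_presets <- function() {
  list(
    `1.5T` = c(theta0 = 40.3,  r0 = 25,  epsilon_ratio = 1.00),
    `3T`   = c(theta0 = 80.6,  r0 = 110, epsilon_ratio = 0.47),
    `7T`   = c(theta0 = 188.1, r0 = 324, epsilon_ratio = 0.30)
  )
}

#' BOLD observation parameters
#'
#' Parameters of the static BOLD signal-change equation.  When `theta0`,
#' `r0` or `epsilon_ratio` are left `NULL` they are filled from the
#' field-strength preset table ([field_strength_presets()]); the derived
#' coefficients k1, k2, k3 are always recomputed from the resolved values and
#' the echo time, so changing `TE` or `field_strength` propagates.
#'
#' @param field_strength One of `"1.5T"`, `"3T"`, `"7T"`.
#' @param TE Echo time (s); required for empirical fits.
#' @param V0 Resting venous blood volume fraction (dimensionless).
#' @param theta0 Frequency offset for fully deoxygenated blood (1/s).
#' @param r0 Slope of intravascular relaxation rate vs oxygen saturation (1/s).
#' @param epsilon_ratio Intra/extravascular signal ratio at rest.
#' @param E0 Resting oxygen extraction fraction used in k1/k2.
#'
#' @return An object of class `bold_params`.
#' @export
bold_params <- function(field_strength = c("3T", "1.5T", "7T"), TE = 0.04,
                        V0 = 0.04, theta0 = NULL, r0 = NULL,
                        epsilon_ratio = NULL, E0 = 0.4) {
  field_strength <- match.arg(field_strength)
  preset <- field_strength_presets()[[field_strength]]
  if (is.null(theta0)) theta0 <- unname(preset["theta0"])
  if (is.null(r0)) r0 <- unname(preset["r0"])
  if (is.null(epsilon_ratio)) epsilon_ratio <- unname(preset["epsilon_ratio"])
  stopifnot(TE > 0, V0 > 0, theta0 > 0, r0 > 0, epsilon_ratio > 0,
            E0 > 0, E0 < 1)
  structure(list(field_strength = field_strength, TE = TE, V0 = V0,
                 theta0 = theta0, r0 = r0, epsilon_ratio = epsilon_ratio,
                 E0 = E0),
            class = "bold_params")
}

#' Oxygen extraction fraction as a function of flow
#'
#' `E(u, E0) = 1 - (1 - E0)^(1/u)`: the fraction of oxygen extracted from
#' inflowing blood at normalized flow `u`, anchored at the resting fraction
#' `E0` for `u = 1`.
#'
#' @param u Normalized cerebral blood flow (> 0); vectorized.
#' @param E0 Resting oxygen extraction fraction, in (0,1).
#' @return Extraction fraction in (0,1), same length as `u`.
#' @export
oxygen_extraction <- function(u, E0) {
  if (any(u <= 0)) stop("flow `u` must be positive")
  if (E0 <= 0 || E0 >= 1) stop("`E0` must lie in (0,1)")
  1 - (1 - E0)^(1 / u)
}

#' BOLD signal coefficients k1, k2, k3
#'
#' Computes the coefficients of the BOLD signal-change equation from the
#' acquisition parameters: `k1 = 4.3 * theta0 * E0 * TE`,
#' `k2 = epsilon_ratio * r0 * E0 * TE`, `k3 = 1 - epsilon_ratio`.
#'
#' @param b A [bold_params()] object.
#' @param epsilon_scale Optional multiplicative factor on `epsilon_ratio`
#'   (used when the intra/extravascular ratio is a fitted log-scale
#'   parameter); default 1.
#' @return Named numeric vector `c(k1, k2, k3)`.
#' @export
bold_coefficients <- function(b, epsilon_scale = 1) {
  stopifnot(inherits(b, "bold_params"))
  eps <- b$epsilon_ratio * epsilon_scale
  c(k1 = 4.3 * b$theta0 * b$E0 * b$TE,
    k2 = eps * b$r0 * b$E0 * b$TE,
    k3 = 1 - eps)
}

#' BOLD signal change from volume and deoxyhemoglobin
#'
#' The static observation equation
#' `lambda(q, v) = V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`,
#' returning the fractional signal change relative to rest (`q = v = 1`
#' gives 0).
#'
#' @param q Normalized deoxyhemoglobin content (> 0); vectorized.
#' @param v Normalized venous blood volume (> 0); vectorized.
#' @param b A [bold_params()] object.
#' @param epsilon_scale Passed to [bold_coefficients()].
#' @return Fractional signal change (dimensionless).
#' @export
bold_signal <- function(q, v, b, epsilon_scale = 1) {
  if (any(v <= 0)) stop("volume `v` must be positive")
  if (any(q <= 0)) stop("deoxyhemoglobin `q` must be positive")
  k <- bold_coefficients(b, epsilon_scale)
  b$V0 * (k[["k1"]] * (1 - q) + k[["k2"]] * (1 - q / v) + k[["k3"]] * (1 - v))
}

#' Balloon-model flow field
#'
#' Time derivatives of the hemodynamic states in natural coordinates:
#' vasodilatory signal `s`, blood flow `u`, volume `v` and deoxyhemoglobin
#' `q`, driven by neuronal activity `x_n`:
#' \deqn{\dot s = x_n - \kappa s - \gamma (u - 1), \quad \dot u = s,}
#' \deqn{\tau \dot v = u - v^{1/\alpha}, \quad
#'       \tau \dot q = u E(u,E_0)/E_0 - v^{1/\alpha} q / v.}
#' The resting point `(s,u,v,q) = (0,1,1,1)` with `x_n = 0` is an exact
#' fixed point.  Internally the composed model propagates `u`, `v`, `q` in
#' log coordinates (see [assemble_circuit()]); this function is the
#' natural-coordinate reference used by that transformation.
#'
#' @param state Numeric vector `c(s, u, v, q)` (or a named vector with those
#'   names).
#' @param x_n Neuronal drive (scalar).
#' @param p A [hemodynamic_params()] object.
#' @return Named numeric vector of derivatives `c(s, u, v, q)`.
#' @export
hemodynamic_flow <- function(state, x_n, p) {
  stopifnot(inherits(p, "hemodynamic_params"), length(state) == 4)
  if (!is.null(names(state))) state <- state[c("s", "u", "v", "q")]
  s <- state[[1]]; u <- state[[2]]; v <- state[[3]]; q <- state[[4]]
  if (u <= 0 || v <= 0 || q <= 0) {
    stop("hemodynamic states u, v, q must be positive")
  }
  fv <- v^(1 / p$alpha)
  c(s = x_n - p$kappa * s - p$gamma * (u - 1),
    u = s,
    v = (u - fv) / p$tau,
    q = (u * oxygen_extraction(u, p$E0) / p$E0 - fv * q / v) / p$tau)
}
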