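# Cross-spectral density estimation from time series via maximum-likelihood
# multivariate autoregressive (MVAR) fits and analytic conversion to spectra.

#' Fit a multivariate autoregressive model by maximum likelihood
#'
#' Conditional maximum-likelihood MVAR estimation, equivalent to ordinary
#' least squares on the lagged regression
#' `y_t = A_1 y_{t-1} + ... + A_p y_{t-p} + e_t`
#' after per-channel mean removal.  The innovation covariance is the ML
#' estimate `Sigma = E'E / (n - p)` from the residuals.  This is a direct
#' (non-Bayesian) fit; it differs slightly from shrinkage-based AR fits and
#' is the convention assumed by [mvar_csd()].
#'
#' @param Y Numeric matrix, rows = time points, columns = channels.
#' @param order AR model order `p` (default 8).
#' @param dt Sampling interval (s).
#' @return Object of class `mvar_model`: list with `A` (list of `p`
#'   lag-coefficient matrices), `Sigma`, `order`, `dt`, `labels`.
#' @export
fit_mvar <- function(Y, order = 8, dt) {
  Y <- as.matrix(Y)
  if (missing(dt) || is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("sampling interval `dt` must be a positive number")
  }
  p <- as.integer(order)
  stopifnot(p >= 1)
  n <- nrow(Y); nc <- ncol(Y)
  if (n <= p * nc + 1) {
    stop(sprintf("need more than %d time points for order %d with %d channels",
                 p * nc + 1, p, nc))
  }
  labels <- colnames(Y)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nc))
  Yc <- sweep(Y, 2, colMeans(Y))
  # lagged design: columns blocked by lag, within lag by channel
  X <- matrix(0, n - p, p * nc)
  for (k in seq_len(p)) {
    X[, (k - 1) * nc + seq_len(nc)] <- Yc[(p - k + 1):(n - k), , drop = FALSE]
  }
  Z <- Yc[(p + 1):n, , drop = FALSE]
  fit <- stats::lm.fit(X, Z)
  if (fit$rank < ncol(X)) stop("rank-deficient lagged regressor matrix")
  Bhat <- fit$coefficients                     # (p*nc) x nc
  res <- fit$residuals
  Sigma <- crossprod(res) / (n - p)
  A <- lapply(seq_len(p), function(k) {
    t(Bhat[(k - 1) * nc + seq_len(nc), , drop = FALSE])
  })
  structure(list(A = A, Sigma = Sigma, order = p, dt = dt, labels = labels),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channel(s), dt = %g s\n",
              x$order, ncol(x$Sigma), x$dt))
  invisible(x)
}

mvar_companion <- function(m) {
  p <- m$order; nc <- ncol(m$Sigma)
  C <- matrix(0, p * nc, p * nc)
  for (k in seq_len(p)) C[seq_len(nc), (k - 1) * nc + seq_len(nc)] <- m$A[[k]]
  if (p > 1) {
    C[nc + seq_len((p - 1) * nc), seq_len((p - 1) * nc)] <-
      diag((p - 1) * nc)
  }
  C
}

#' Analytic cross-spectral density of an MVAR model
#'
#' One-sided per-Hz spectrum of a stationary MVAR process:
#' `S(f) = 2 dt H(f) Sigma H(f)^H` with
#' `H(f) = (I - sum_k A_k exp(-2 pi i f k dt))^-1`.
#' With this convention the integral of each diagonal over `(0, 1/(2 dt)]`
#' equals the corresponding process variance, matching the convention of
#' [predict_csd()].
#'
#' @param m An `mvar_model`.
#' @param frequencies Frequency grid (Hz), at most the Nyquist `1/(2 dt)`.
#' @return A `dcm_csd`.
#' @export
mvar_csd <- function(m, frequencies) {
  stopifnot(inherits(m, "mvar_model"))
  f <- check_grid(frequencies)
  if (max(f) > 1 / (2 * m$dt) + 1e-12) {
    stop("frequency grid exceeds the Nyquist frequency of the model")
  }
  rho <- max(Mod(eigen(mvar_companion(m), only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("nonstationary MVAR model (companion spectral radius %.4f)",
                 rho))
  }
  nc <- ncol(m$Sigma)
  S <- array(0 + 0i, c(length(f), nc, nc))
  I <- diag(nc)
  for (k in seq_along(f)) {
    Afree <- I
    for (l in seq_len(m$order)) {
      Afree <- Afree - m$A[[l]] * exp(-2i * pi * f[k] * l * m$dt)
    }
    H <- solve(Afree)
    S[k, , ] <- 2 * m$dt * H %*% m$Sigma %*% Conj(t(H))
  }
  new_csd(S, f, m$labels)
}

#' Estimate the cross-spectral density of observed time series
#'
#' Pipeline used on measured (or simulated) region time series: per-channel
#' mean and linear-trend removal, maximum-likelihood MVAR fit of fixed order
#' (default 8), and analytic conversion to the cross-spectral density on the
#' requested grid.  Deterministic given its inputs.
#'
#' @param Y Numeric matrix, rows = time points, columns = channels
#'   (column names become channel labels).
#' @param frequencies Frequency grid (Hz); defaults to the fMRI band
#'   truncated at the data Nyquist.
#' @param order MVAR order (default 8).
#' @param dt Sampling interval in seconds (the repetition time for fMRI).
#' @return A `dcm_csd`.
#' @export
estimate_csd <- function(Y, frequencies = NULL, order = 8, dt) {
  Y <- as.matrix(Y)
  if (missing(dt) || is.null(dt)) {
    dt <- attr(Y, "TR")
    if (is.null(dt)) stop("sampling interval `dt` must be supplied")
  }
  if (is.null(frequencies)) {
    frequencies <- frequency_grid(nyquist = 1 / (2 * dt))
  }
  t <- seq_len(nrow(Y))
  Yd <- apply(Y, 2, function(y) stats::lm.fit(cbind(1, t), y)$residuals)
  colnames(Yd) <- colnames(Y)
  m <- fit_mvar(Yd, order = order, dt = dt)
  mvar_csd(m, frequencies)
}
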