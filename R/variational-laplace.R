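# Variational Laplace inversion: Gaussian posterior over parameters plus
# log-precision hyperparameters on the prediction error, optimized by a
# damped Gauss-Newton ascent on the free energy.

#' Gaussian prior over model parameters
#'
#' Diagonal Gaussian prior with per-parameter tunable flags.  Parameters
#' with zero variance are fixed at their mean and removed from the tunable
#' subspace (they contribute no KL term); parameters with `tunable = FALSE`
#' are frozen at their (possibly nonzero) mean.
#'
#' @param mean Named numeric vector of prior means.
#' @param var Prior variances (named like `mean`, or scalar recycled).
#' @param tunable Logical flags (named like `mean`, or scalar recycled).
#' @return Object of class `dcm_prior`.
#' @export
gaussian_prior <- function(mean, var, tunable = TRUE) {
  stopifnot(!is.null(names(mean)), !anyDuplicated(names(mean)))
  var <- rep_len(var, length(mean))
  tunable <- rep_len(tunable, length(mean))
  if (any(var < 0)) stop("prior variances must be nonnegative")
  names(var) <- names(tunable) <- names(mean)
  structure(list(mean = mean, var = var, tunable = tunable),
            class = "dcm_prior")
}

#' Default prior for a composed model
#'
#' Reads means, variances and tunable flags from the model's parameter
#' table: zero-mean connection parameters with variance 1/128, log
#' transit-time factors with variance 1/256, noise log-amplitudes centered
#' on the model defaults with variance 1/64, spectral exponent fixed.
#'
#' @param model A `dcm_model`.
#' @return A `dcm_prior`.
#' @export
default_prior <- function(model) {
  stopifnot(inherits(model, "dcm_model"))
  p <- model$params
  gaussian_prior(stats::setNames(p$value, p$name), p$prior_var, p$tunable)
}

#' @export
print.dcm_prior <- function(x, ...) {
  cat(sprintf("<dcm_prior> %d parameter(s), %d tunable\n",
              length(x$mean), length(tunable_names(x))))
  invisible(x)
}

# names of parameters actually optimized
tunable_names <- function(prior) {
  names(prior$mean)[prior$tunable & prior$var > 0]
}

#' Precision hyperparameters on the prediction error
#'
#' The error precision is modelled as `Pi(lambda) = sum_k exp(lambda_k) Q_k`
#' with diagonal precision components `Q_k` (given as vectors of diagonal
#' weights over features) and Gaussian hyperpriors on the log-precisions.
#' The default is a single identity component with hyperprior
#' `lambda ~ N(0, 1)`.
#'
#' @param Q List of diagonal weight vectors (or `NULL` for one identity
#'   component, resolved against the feature length at fit time).
#' @param mean,var Hyperprior means and variances (length = number of
#'   components).
#' @param tunable Logical; `FALSE` fixes the log-precisions at `mean`
#'   (known-noise setting).
#' @return Object of class `dcm_hyper`.
#' @export
hyperparameters <- function(Q = NULL, mean = 0, var = 1, tunable = TRUE) {
  k <- if (is.null(Q)) length(mean) else length(Q)
  mean <- rep_len(mean, k); var <- rep_len(var, k)
  tunable <- rep_len(tunable, k)
  stopifnot(all(var >= 0))
  structure(list(Q = Q, mean = mean, var = var, tunable = tunable),
            class = "dcm_hyper")
}

resolve_hyper <- function(hyper, n_features) {
  if (is.null(hyper)) hyper <- hyperparameters()
  stopifnot(inherits(hyper, "dcm_hyper"))
  if (is.null(hyper$Q)) {
    hyper$Q <- rep(list(rep(1, n_features)), length(hyper$mean))
  }
  lens <- vapply(hyper$Q, length, integer(1))
  if (any(lens != n_features)) {
    stop("precision components must match the feature length")
  }
  hyper
}

precision_diag <- function(hyper, lambda) {
  Pi <- numeric(length(hyper$Q[[1]]))
  for (k in seq_along(hyper$Q)) Pi <- Pi + exp(lambda[k]) * hyper$Q[[k]]
  if (any(Pi <= 0)) stop("precision must be positive definite")
  Pi
}

#' Vectorize a cross-spectral density into real features
#'
#' Deterministic stacking `[Re(S); Im(S)]` over the array in `(frequency,
#' row, column)` order, yielding `2 * n_f * n_ch^2` real features.
#' [devectorize_csd()] inverts the map exactly.
#'
#' @param csd A `dcm_csd`.
#' @return Numeric feature vector.
#' @export
vectorize_csd <- function(csd) {
  stopifnot(inherits(csd, "dcm_csd"))
  c(as.numeric(Re(csd$values)), as.numeric(Im(csd$values)))
}

#' Reconstruct a cross-spectral density from its feature vector
#'
#' @param x Feature vector from [vectorize_csd()].
#' @param frequencies Frequency grid of the original CSD.
#' @param labels Channel labels.
#' @return A `dcm_csd`.
#' @export
devectorize_csd <- function(x, frequencies, labels) {
  nf <- length(frequencies); nc <- length(labels)
  stopifnot(length(x) == 2 * nf * nc^2)
  half <- length(x) / 2
  values <- array(complex(real = x[seq_len(half)],
                          imaginary = x[half + seq_len(half)]),
                  c(nf, nc, nc))
  new_csd(values, frequencies, labels)
}

# central finite-difference Jacobian of a feature prediction with
# prior-whitened steps; halves a column's step (up to 4 times) if the
# model is unstable at the perturbed point
fd_feature_jacobian <- function(predict, theta, tunable, h) {
  J <- NULL
  for (j in seq_along(tunable)) {
    nm <- tunable[j]; hj <- h[j]
    col <- NULL
    for (try in 1:5) {
      tp <- theta; tp[nm] <- tp[nm] + hj
      tm <- theta; tm[nm] <- tm[nm] - hj
      gp <- tryCatch(predict(tp), error = function(e) NULL)
      gm <- tryCatch(predict(tm), error = function(e) NULL)
      if (!is.null(gp) && !is.null(gm)) {
        col <- (gp - gm) / (2 * hj)
        break
      }
      hj <- hj / 2
    }
    if (is.null(col)) {
      stop(sprintf("model unstable around parameter '%s' during Jacobian", nm))
    }
    if (is.null(J)) J <- matrix(0, length(col), length(tunable),
                                dimnames = list(NULL, tunable))
    J[, j] <- col
  }
  J
}

#' Jacobian of the predicted CSD features with respect to the parameters
#'
#' Derivative of `vectorize_csd(predict_csd(model, theta))` with respect to
#' the tunable parameters.  The default backend is central finite
#' differences with steps of `step` on the prior-whitened scale
#' (`step * sqrt(prior variance)` per parameter); `method = "forward"` is a
#' cheaper one-sided alternative satisfying the same contract to lower
#' order.  Non-tunable parameters contribute no column.
#'
#' @param model A `dcm_model`.
#' @param theta Parameter vector.
#' @param frequencies Frequency grid.
#' @param prior A `dcm_prior` supplying the tunable set and whitening
#'   scales (default [default_prior()]).
#' @param step Relative step on the whitened scale.
#' @param method `"central"` (default) or `"forward"`.
#' @return Matrix `(n_features x n_tunable)` with column names.
#' @export
csd_parameter_jacobian <- function(model, theta = pack_parameters(model),
                                   frequencies = frequency_grid(),
                                   prior = default_prior(model),
                                   step = 1e-3,
                                   method = c("central", "forward")) {
  method <- match.arg(method)
  theta <- check_theta(model, theta)
  tn <- tunable_names(prior)
  h <- step * sqrt(prior$var[tn])
  predict <- function(th) vectorize_csd(predict_csd(model, th, frequencies))
  if (method == "central") {
    return(fd_feature_jacobian(predict, theta, tn, h))
  }
  g0 <- predict(theta)
  J <- matrix(0, length(g0), length(tn), dimnames = list(NULL, tn))
  for (j in seq_along(tn)) {
    tp <- theta; tp[tn[j]] <- tp[tn[j]] + h[j]
    J[, j] <- (predict(tp) - g0) / h[j]
  }
  J
}

logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

# Fisher-scoring M-step on the log-precisions; returns updated lambda and
# its posterior covariance.  rq = diag(J Sigma_q J') precomputed.
hyper_mstep <- function(e, rq, hyper, lambda, max_it = 8) {
  free <- which(hyper$tunable & hyper$var > 0)
  nk <- length(lambda)
  H <- matrix(0, nk, nk)
  for (it in seq_len(max(1, max_it))) {
    Pi <- precision_diag(hyper, lambda)
    g <- numeric(nk)
    for (k in seq_len(nk)) {
      Pk <- exp(lambda[k]) * hyper$Q[[k]]
      g[k] <- 0.5 * (sum(Pk / Pi) - sum(Pk * e^2) - sum(Pk * rq))
      if (hyper$var[k] > 0) {
        g[k] <- g[k] - (lambda[k] - hyper$mean[k]) / hyper$var[k]
      }
      for (l in seq_len(k)) {
        Pl <- exp(lambda[l]) * hyper$Q[[l]]
        H[k, l] <- H[l, k] <- -0.5 * sum(Pk * Pl / Pi^2)
      }
      if (hyper$var[k] > 0) H[k, k] <- H[k, k] - 1 / hyper$var[k]
    }
    if (!length(free)) break
    dl <- solve(-H[free, free, drop = FALSE], g[free])
    dl <- pmin(4, pmax(-4, dl))
    # clamp: precisions beyond exp(+-32) are numerically indistinguishable
    # from a perfect (or hopeless) fit and would overflow downstream
    lambda[free] <- pmin(32, pmax(-32, lambda[free] + dl))
    if (max(abs(dl)) < 1e-4) break
  }
  Sl <- if (length(free)) {
    solve(-H[free, free, drop = FALSE])
  } else {
    matrix(0, 0, 0)
  }
  list(lambda = lambda, Sigma_lambda = Sl, free = free)
}

#' Variational free energy of the linearized model
#'
#' Exact evidence lower bound of the locally linearized Gaussian model.
#' Term grouping: accuracy
#' `-1/2 e' Pi e - 1/2 tr(Sigma_q J' Pi J) + 1/2 ln|Pi| - n_e/2 ln(2 pi)`
#' minus the closed-form Gaussian KL divergences of the parameter posterior
#' from its prior and of the hyperparameter posterior from its hyperprior.
#' When `Sigma_q` is the Gauss-Newton posterior covariance
#' `(J' Pi J + Sigma_p^-1)^-1`, the parameter trace terms collapse and this
#' equals the familiar accuracy-minus-complexity form; on linear-Gaussian
#' problems the maximized value equals the analytic log evidence.
#'
#' @param e Residual feature vector (data minus prediction at the posterior
#'   mean).
#' @param J Feature Jacobian (`n_features x n_tunable`).
#' @param mu Posterior mean of the tunable parameters (named).
#' @param Sigma_q Posterior covariance (tunable subspace).
#' @param prior A `dcm_prior`.
#' @param hyper A `dcm_hyper` (resolved; see [hyperparameters()]).
#' @param lambda Log-precision values.
#' @param Sigma_lambda Posterior covariance of the tunable log-precisions.
#' @return Scalar free energy.
#' @export
free_energy <- function(e, J, mu, Sigma_q, prior, hyper, lambda,
                        Sigma_lambda = NULL) {
  hyper <- resolve_hyper(hyper, length(e))
  tn <- tunable_names(prior)
  stopifnot(length(mu) == length(tn), all(dim(Sigma_q) == length(tn)))
  Pi <- precision_diag(hyper, lambda)
  rq <- if (length(tn)) rowSums((J %*% Sigma_q) * J) else numeric(length(e))
  acc <- -0.5 * sum(Pi * e^2) - 0.5 * sum(Pi * rq) +
    0.5 * sum(log(Pi)) - 0.5 * length(e) * log(2 * pi)
  klp <- 0
  if (length(tn)) {
    v <- prior$var[tn]; m <- prior$mean[tn]
    klp <- 0.5 * (sum(diag(Sigma_q) / v) + sum((mu - m)^2 / v) -
                    length(tn) + sum(log(v)) - logdet_chol(Sigma_q))
  }
  klh <- 0
  free <- which(hyper$tunable & hyper$var > 0)
  if (length(free)) {
    if (is.null(Sigma_lambda)) {
      rqe <- rq
      ms <- hyper_mstep(e, rqe, hyper, lambda, max_it = 0)
      Sigma_lambda <- ms$Sigma_lambda
    }
    v <- hyper$var[free]; m <- hyper$mean[free]; l <- lambda[free]
    klh <- 0.5 * (sum(diag(Sigma_lambda) / v) + sum((l - m)^2 / v) -
                    length(free) + sum(log(v)) - logdet_chol(Sigma_lambda))
  }
  acc - klp - klh
}

# assemble full parameter vector from tunable subvector
full_theta <- function(prior, mu) {
  th <- prior$mean
  th[names(mu)] <- mu
  th
}

#' One damped Gauss-Newton update of the variational state
#'
#' Proposes `delta_mu = (J' Pi J + Sigma_p^-1 + damping I)^-1 (J' Pi e -
#' Sigma_p^-1 (mu - m_p))`, re-estimates the log-precisions at the proposed
#' point by Fisher scoring, and evaluates the free energy.  Proposals that
#' decrease the free energy (or fail, e.g. through model instability) are
#' rejected: the state is returned unchanged with the damping multiplied by
#' 4.  Accepted proposals halve the damping (down to its floor).
#'
#' @param state List with elements `mu`, `lambda`, `F`, `damping` (as
#'   produced by [vl_invert()] internally).
#' @param J Feature Jacobian at `state$mu`.
#' @param y Data feature vector.
#' @param predict Prediction function `function(theta_full)`.
#' @param prior A `dcm_prior`.
#' @param hyper A resolved `dcm_hyper`.
#' @return Updated state list with an `accepted` flag.
#' @export
vl_update_step <- function(state, J, y, predict, prior, hyper) {
  tn <- tunable_names(prior)
  iC <- 1 / prior$var[tn]
  mp <- prior$mean[tn]
  Pi <- precision_diag(hyper, state$lambda)
  JP <- t(J * Pi)                        # J' Pi
  H <- JP %*% J + diag(iC, length(tn))
  Hd <- H + diag(state$damping, length(tn))
  e <- y - predict(full_theta(prior, state$mu))
  g <- drop(JP %*% e) - iC * (state$mu - mp)
  dmu <- drop(solve(Hd, g))
  mu_new <- state$mu + dmu

  proposal <- tryCatch({
    e_new <- y - predict(full_theta(prior, mu_new))
    lambda_new <- state$lambda
    Sq <- chol2inv(chol(JP %*% J + diag(iC, length(tn))))
    for (rep in 1:2) {
      rq <- rowSums((J %*% Sq) * J)
      ms <- hyper_mstep(e_new, rq, hyper, lambda_new)
      lambda_new <- ms$lambda
      Pi_new <- precision_diag(hyper, lambda_new)
      Sq <- chol2inv(chol(t(J * Pi_new) %*% J + diag(iC, length(tn))))
    }
    Fn <- free_energy(e_new, J, mu_new, Sq, prior, hyper, lambda_new,
                      ms$Sigma_lambda)
    list(F = Fn, mu = mu_new, lambda = lambda_new, Sigma_q = Sq)
  }, error = function(err) NULL)

  if (!is.null(proposal) && is.finite(proposal$F) && proposal$F > state$F) {
    state$mu <- proposal$mu
    state$lambda <- proposal$lambda
    state$Sigma_q <- proposal$Sigma_q
    state$dF <- proposal$F - state$F
    state$F <- proposal$F
    state$damping <- max(state$damping / 2, state$damping_floor)
    state$accepted <- TRUE
  } else {
    state$damping <- state$damping * 4
    state$accepted <- FALSE
    state$dF <- NA_real_
  }
  state
}

#' Invert a generative feature model by variational Laplace
#'
#' Generic engine: given a data feature vector, a prediction function and
#' Gaussian priors, maximizes the free energy over the posterior mean,
#' covariance and error log-precisions by damped Gauss-Newton iteration.
#' Deterministic given its inputs.  [dcm_invert()] wraps this engine with
#' the CSD forward model.
#'
#' @param y Data feature vector.
#' @param predict `function(theta_full)` returning predicted features;
#'   should signal an error for invalid (e.g. dynamically unstable)
#'   parameters.
#' @param prior A `dcm_prior` over the full parameter vector.
#' @param hyper A `dcm_hyper` (default: single identity component,
#'   hyperprior N(0, 1)).
#' @param opts List of optimizer settings: `max_iter` (128), `tol` (1e-2 on
#'   successive accepted free-energy changes), `tol_window` (4 consecutive
#'   small changes), `damping_init` (1/32), `damping_floor` (1e-8),
#'   `damping_max` (1e8), `fd_step` (1e-3, prior-whitened), `verbose`.
#' @return Object of class `dcm_posterior`.
#' @export
vl_invert <- function(y, predict, prior, hyper = NULL, opts = list()) {
  o <- utils::modifyList(list(max_iter = 128, tol = 1e-2, tol_window = 4,
                              damping_init = 1 / 32, damping_floor = 1e-8,
                              damping_max = 1e8, fd_step = 1e-3,
                              verbose = FALSE),
                         opts)
  stopifnot(inherits(prior, "dcm_prior"))
  hyper <- resolve_hyper(hyper, length(y))
  tn <- tunable_names(prior)
  if (!length(tn)) stop("no tunable parameters with positive prior variance")
  iC <- 1 / prior$var[tn]
  h <- o$fd_step * sqrt(prior$var[tn])

  mu <- prior$mean[tn]
  lambda <- hyper$mean
  g0 <- tryCatch(predict(full_theta(prior, mu)), error = function(e) {
    stop("prediction failed at the prior mean: ", conditionMessage(e),
         call. = FALSE)
  })
  stopifnot(length(g0) == length(y))
  e <- y - g0

  J <- fd_feature_jacobian(predict, full_theta(prior, mu), tn, h)
  # initialize lambda and Sigma_q jointly at the prior mean
  Sq <- chol2inv(chol(t(J) %*% J + diag(iC, length(tn))))
  lambda_state <- lambda
  for (rep in 1:3) {
    rq <- rowSums((J %*% Sq) * J)
    ms <- hyper_mstep(e, rq, hyper, lambda_state)
    lambda_state <- ms$lambda
    Pi <- precision_diag(hyper, lambda_state)
    Sq <- chol2inv(chol(t(J * Pi) %*% J + diag(iC, length(tn))))
  }
  F0 <- free_energy(e, J, mu, Sq, prior, hyper, lambda_state,
                    ms$Sigma_lambda)

  state <- list(mu = mu, lambda = lambda_state, Sigma_q = Sq, F = F0,
                damping = o$damping_init, damping_floor = o$damping_floor,
                dF = NA_real_, accepted = NA)
  trace <- data.frame(iter = 0L, F = F0, damping = state$damping,
                      accepted = NA, dF = NA_real_)
  small <- 0L
  converged <- FALSE
  for (it in seq_len(o$max_iter)) {
    state <- vl_update_step(state, J, y, predict, prior, hyper)
    trace <- rbind(trace, data.frame(iter = it, F = state$F,
                                     damping = state$damping,
                                     accepted = state$accepted,
                                     dF = state$dF))
    if (o$verbose) {
      message(sprintf("it %3d  F = %12.4f  damping = %.3g  %s", it, state$F,
                      state$damping,
                      if (isTRUE(state$accepted)) "accepted" else "rejected"))
    }
    if (isTRUE(state$accepted)) {
      J <- fd_feature_jacobian(predict, full_theta(prior, state$mu), tn, h)
      small <- if (abs(state$dF) < o$tol) small + 1L else 0L
      if (small >= o$tol_window) {
        converged <- TRUE
        break
      }
    } else if (state$damping > o$damping_max) {
      converged <- TRUE     # damping exhausted: F cannot be improved locally
      break
    }
  }

  mean_full <- full_theta(prior, state$mu)
  dimnames(state$Sigma_q) <- list(tn, tn)
  structure(list(mean = mean_full, cov = state$Sigma_q,
                 lambda = state$lambda, F = state$F, trace = trace,
                 converged = converged, tunable = tn,
                 data_hash = rlang::hash(y)),
            class = "dcm_posterior")
}

#' Invert a spectral DCM on an observed cross-spectral density
#'
#' Fits the composed generative model to a data CSD (typically from
#' [estimate_csd()]) by variational Laplace on the stacked real/imaginary
#' spectral features.  The frequency grid of the prediction is taken from
#' the data.
#'
#' @param data_csd A `dcm_csd` of the measured time series.
#' @param model A `dcm_model` with matching channel count.
#' @param prior A `dcm_prior` (default [default_prior()]).
#' @param hyper Optional `dcm_hyper`.
#' @param opts Optimizer options, see [vl_invert()].
#' @param perturb Optional expansion-point perturbation scale forwarded to
#'   [predict_csd()].
#' @return A `dcm_posterior`; element `mean` holds the full named parameter
#'   vector, `cov` the posterior covariance over tunable parameters, `F`
#'   the free energy, `trace` the iteration history and `converged` the
#'   convergence flag.
#' @export
dcm_invert <- function(data_csd, model, prior = default_prior(model),
                       hyper = NULL, opts = list(), perturb = 0) {
  stopifnot(inherits(data_csd, "dcm_csd"), inherits(model, "dcm_model"))
  if (length(data_csd$labels) != model$n_channels) {
    stop("data CSD and model have different channel counts")
  }
  grid <- data_csd$frequencies
  predict <- function(theta) {
    vectorize_csd(predict_csd(model, theta, grid, perturb = perturb))
  }
  y <- vectorize_csd(data_csd)
  if (is.null(hyper)) {
    # Spectral estimates have errors proportional to the spectrum itself
    # (the variance of periodogram-type estimators scales with S(f)^2), so
    # the default precision component weights every feature by the inverse
    # squared per-frequency scale of the data CSD: a relative-error noise
    # model with a single overall log-precision.
    sf <- apply(data_csd$values, 1, function(M) mean(Mod(M)))
    sf <- pmax(sf, 1e-12 * max(sf))
    w <- rep(rep(1 / sf^2, length(data_csd$labels)^2), 2)
    hyper <- hyperparameters(Q = list(w))
  }
  post <- vl_invert(y, predict, prior, hyper, opts)
  post$frequencies <- as.numeric(grid)
  post$labels <- model$labels
  post
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("<dcm_posterior> F = %.4f, %s after %d iteration(s)\n", x$F,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              max(x$trace$iter)))
  cat("  posterior means (tunable):\n")
  print(round(x$mean[x$tunable], 4))
  invisible(x)
}

#' Write an inversion report to JSON
#'
#' Serializes posterior means, covariance, log-precisions, free energy,
#' iteration trace and convergence flag as a structured JSON document.
#'
#' @param post A `dcm_posterior`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "dcm_posterior"))
  obj <- list(schema_version = "1.0",
              mean = as.list(post$mean),
              tunable = post$tunable,
              cov = unclass(post$cov),
              lambda = post$lambda,
              F = post$F,
              converged = post$converged,
              data_hash = post$data_hash,
              trace = post$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an inversion report written by [write_posterior()]
#'
#' @param path JSON file path.
#' @return A `dcm_posterior`.
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- as.matrix(obj$cov)
  dimnames(cov) <- list(obj$tunable, obj$tunable)
  structure(list(mean = unlist(obj$mean), cov = cov, lambda = obj$lambda,
                 F = obj$F, trace = obj$trace, converged = obj$converged,
                 tunable = obj$tunable, data_hash = obj$data_hash),
            class = "dcm_posterior")
}
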