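# Shared builders and caches for the test suite.  Everything is generated
# in code; expensive simulate/estimate/invert results are memoized so that
# several test files can reuse the same seeded experiments.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# scalar Ornstein-Uhlenbeck model: dx = -l0 x + noise, observed directly,
# flat unit state-noise spectrum, no measurement noise
ou_model <- function(l0 = 0.4, meas = 0) {
  new_dcm_model(
    flow = function(x, th) -th[["l0"]] * x,
    obs = function(x, th) x,
    params = data.frame(name = "l0", value = l0, tunable = FALSE,
                        prior_var = 0),
    n_states = 1, n_regions = 1, n_channels = 1,
    noise_spectra = function(th, f) {
      list(Sf = matrix(1, length(f), 1), Sg = matrix(meas, length(f), 1))
    })
}

# three-region demonstration circuit with the generative connectivity
demo_theta <- function(model) {
  th <- pack_parameters(model)
  th[c("a_1_2", "a_2_1", "a_3_2", "a_2_3")] <- c(-0.2, 0.4, -0.3, 0.2)
  th
}

get_scenario <- function(seed) {
  memo(paste0("scenario_", seed), default_scenario(seed))
}

scenario_csd <- function(seed) {
  memo(paste0("csd_", seed), {
    scen <- get_scenario(seed)
    estimate_csd(scen$data, frequency_grid(nyquist = 1 / (2 * scen$TR)),
                 dt = scen$TR)
  })
}

# full-prior recovery inversion for one seed
recovery_fit <- function(seed) {
  memo(paste0("recovery_", seed), {
    scen <- get_scenario(seed)
    dcm_invert(scenario_csd(seed), scen$model, scen$prior)
  })
}

# inversions of the Table-2-style model family for one seed
selection_fits <- function(seed) {
  memo(paste0("selection_", seed), {
    scen <- get_scenario(seed)
    csd <- scenario_csd(seed)
    pr <- scen$prior
    structures <- list(
      gt = exclude_parameter(pr, c("a_1_3", "a_3_1")),
      drop_a12 = exclude_parameter(pr, c("a_1_3", "a_3_1", "a_1_2")),
      drop_a21 = exclude_parameter(pr, c("a_1_3", "a_3_1", "a_2_1")),
      drop_a23 = exclude_parameter(pr, c("a_1_3", "a_3_1", "a_2_3")),
      drop_a32 = exclude_parameter(pr, c("a_1_3", "a_3_1", "a_3_2")),
      full = pr)
    lapply(structures, function(p) dcm_invert(csd, scen$model, p))
  })
}

rel_frobenius <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

expect_hermitian_psd <- function(csd, tol = 1e-12) {
  for (k in seq_along(csd$frequencies)) {
    M <- csd$values[k, , ]
    expect_lt(max(Mod(M - Conj(t(M)))), 1e-10)
    ev <- eigen((M + Conj(t(M))) / 2, only.values = TRUE)$values
    expect_gte(min(Re(ev)), -tol * max(abs(Re(ev)), 1))
  }
}

# independently written balloon + BOLD flow in natural coordinates,
# used as a substitution oracle (kept separate from the package's
# log-space implementation)
oracle_balloon <- function(s, u, v, q, xn, kappa, gamma, tau, alpha, E0) {
  E <- 1 - (1 - E0)^(1 / u)
  c(xn - kappa * s - gamma * (u - 1),
    s,
    (u - v^(1 / alpha)) / tau,
    (u * E / E0 - v^(1 / alpha) * q / v) / tau)
}
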