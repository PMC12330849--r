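---
title: "Spectral DCM in spectraldcm: model, inversion and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral DCM in spectraldcm: model, inversion and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraldcm)
```

# The generative model

Spectral dynamic causal modelling (spectral DCM) infers directed
("effective") connectivity between brain regions from the *cross-spectral
density* (CSD) of stationary resting-state signals, rather than from the
time series themselves.  The generative model composed by
`assemble_circuit()` has three layers per region:

**Neuronal dynamics.** Hidden neuronal activity is a linear neural mass,
$\dot x = A x$, where element $A_{yx}$ (row = target, column = source) is
the rate in Hz at which region $x$ drives region $y$.  Self-connections are
parameterized as $A_{ii} = -\tfrac12 e^{a_{ii}}$ with $a_{ii}$ free and
prior mean 0, so the diagonal is negative for any parameter value and the
circuit is stable at the prior mean.  There are no exogenous inputs in the
default resting-state model.

**Hemodynamics.** Each region's activity drives a balloon model:
vasodilatory signal $\dot s = x - \kappa s - \gamma(u - 1)$, blood flow
$\dot u = s$, volume $\tau \dot v = u - v^{1/\alpha}$ and deoxyhemoglobin
$\tau \dot q = u E(u, E_0)/E_0 - v^{1/\alpha} q/v$, with oxygen extraction
$E(u, E_0) = 1 - (1 - E_0)^{1/u}$.  Internally $u$, $v$, $q$ are propagated
as logarithms: positivity becomes structural, and the resting steady state
$(x, s, \ln u, \ln v, \ln q) = 0$ is the origin, which is the expansion
point of the spectral linearization.  Fitted hemodynamic parameters act
multiplicatively: the region-specific transit time is
$\tau_r = \tau\, e^{\theta_{\tau,r}}$ with $\theta_{\tau,r}$ the tunable
log-factor.

**Observation.** The BOLD signal change is the static map
$\lambda(q, v) = V_0 \left[k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)\right]$
with $k_1 = 4.3\,\theta_0 E_0\,\mathrm{TE}$,
$k_2 = \epsilon r_0 E_0 \,\mathrm{TE}$, $k_3 = 1 - \epsilon$.  The
coefficients are recomputed from the echo time and a field-strength preset
($\theta_0$, $r_0$, $\epsilon$ for 1.5T/3T/7T); the shipped preset numbers
are literature-derived placeholders and deliberately configurable, because
published estimates vary.  The observation is reported in **percent signal
change** ($100\,\lambda$, with $V_0 = 0.04$).  We chose the percent
convention because it is the scale on which resting-state BOLD fluctuations
have magnitudes of order 0.1–1: demanding fluctuations of that size in raw
fractional units would push the balloon model far outside the regime where
the fixed-point linearization below is meaningful.

Default parameter values (all configurable, all prior means):
$\kappa = 0.64\,s^{-1}$, $\gamma = 0.32\,s^{-1}$, $\tau = 2\,s$,
$\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$, $\mathrm{TE} = 40$ ms.

# From dynamics to cross-spectra

`linearize()` evaluates the Jacobian $J$ of the composed flow and the
observation gradient $G$ at the resting fixed point (analytically for the
built-in circuit, by central differences for user-supplied models) and
verifies that $J$ is Hurwitz-stable; an unstable parameter vector is an
explicit error naming the offending eigenvalue.  The first-order response
of the observations to endogenous fluctuations entering the neuronal states
(input map $B$) is then the transfer function
$$K(f) = G\,(2\pi i f I - J)^{-1} B,$$
computed by direct complex solves per frequency.  We deliberately avoid an
eigendecomposition here: at the fixed point the per-region hemodynamic
blocks are identical, so $J$ has (near-)degenerate eigenvalues and an
eigenvector basis can be arbitrarily ill-conditioned, whereas the resolvent
solve is well-posed for any stable $J$.  An optional Gaussian perturbation
of the expansion point (scale $10^{-10}$) is retained as a robustness
device for differentiation backends that do require an eigenbasis.

Endogenous and measurement noise are power laws in frequency.  The state
noise entering region $r$ has one-sided density
$(e^{\alpha_g} + e^{\alpha_r}) f^{-\beta}$ — a global amplitude shared by
all regions plus a region-specific one — and the measurement noise has
density $e^{\alpha_m} f^{-\beta}$, identical across channels.  Both are
diagonal (uncorrelated noise).  The predicted CSD is
$$S_y(f) = K(f)\, S_{\varepsilon_f}(f)\, K(f)^H + S_{\varepsilon_g}(f),$$
Hermitian and positive semidefinite at every frequency (property-tested
over random stable circuits).

All spectra in the package use the **one-sided, per-Hz** convention: the
integral of a diagonal over $(0, f_{\mathrm{Nyq}}]$ is the process
variance.  Public interfaces use frequency $f$ in Hz; $2\pi$ factors are
internal.  The default analysis grid is 32 linearly spaced frequencies on
$[1/128, 0.25]$ Hz — the conventional resting-state band, with the upper
edge at the Nyquist frequency of a TR = 2 s acquisition; both band and
resolution are free choices of this package (truncated automatically at the
data Nyquist when attached to data).

# Estimating cross-spectra from time series

`estimate_csd()` removes each channel's mean and linear trend, fits a
multivariate autoregressive model of fixed order 8 by conditional maximum
likelihood (ordinary least squares on the lagged regression, innovation
covariance from the residuals), and converts it analytically:
$$\hat S(f) = 2\,\Delta t\, H(f)\, \Sigma\, H(f)^H, \qquad
H(f) = \Big(I - \sum_{k=1}^{8} A_k e^{-2\pi i f k \Delta t}\Big)^{-1}.$$
The factor $2\Delta t$ makes the estimator share the forward model's
one-sided per-Hz convention; a cross-module test verifies the two sides
agree on white noise and on simulated linear systems.  This is a direct ML
fit, not a shrinkage/Bayesian AR fit; the choice is simple and transparent
but gives the estimate more realization variance than a regularized fit
would (this matters for model comparison; see *Limitations*).  No
windowing or tapering is applied — an AR estimator needs none.

# Variational Laplace inversion

`dcm_invert()` stacks the real and imaginary parts of the CSD over
(frequency, row, column) into a real feature vector (complex-step-free and
exactly invertible; Hermitian diagonals contribute zeros to the imaginary
block) and maximizes a variational free energy over a Gaussian posterior
$q(\theta) = N(\mu, \Sigma_q)$ on the tunable parameters plus log-precision
hyperparameters $\lambda$ on the prediction error.

The free energy implemented in `free_energy()` is the exact evidence lower
bound of the locally linearized Gaussian model,
$$F = -\tfrac12 e^\top \Pi e - \tfrac12 \mathrm{tr}(\Sigma_q J^\top \Pi J)
      + \tfrac12 \ln|\Pi| - \tfrac{n_e}{2}\ln 2\pi
      - D_{KL}\!\left[q(\theta)\,\|\,p(\theta)\right]
      - D_{KL}\!\left[q(\lambda)\,\|\,p(\lambda)\right],$$
with $\Pi(\lambda) = \sum_k e^{\lambda_k} Q_k$.  When $\Sigma_q$ is the
Gauss–Newton covariance $(J^\top \Pi J + \Sigma_p^{-1})^{-1}$ the parameter
trace terms collapse into the familiar accuracy-minus-complexity form; on
linear-Gaussian problems the maximized $F$ equals the analytic log evidence
(this is asserted to $10^{-4}$ in the tests, and the posterior matches the
conjugate closed form to $10^{-6}$).

Optimization is a damped Gauss–Newton ascent:
$\Delta\mu = (J^\top \Pi J + \Sigma_p^{-1} + \delta I)^{-1}
(J^\top \Pi e - \Sigma_p^{-1}(\mu - m_p))$, with the log-precisions
re-estimated at each proposal by Fisher-scored Newton steps (capped at 4
per inner step and clamped to $|\lambda| \le 32$ to keep $e^\lambda$
finite).  Proposals that decrease $F$ are rejected — the state is untouched
and the damping $\delta$ is multiplied by 4; accepted steps halve it (floor
$10^{-8}$, initial $1/32$).  Iteration stops after 4 consecutive accepted
changes below $10^{-2}$, when damping exhausts a locally unimprovable
optimum, or at 128 iterations; the monotonicity of $F$ over accepted steps
is asserted for every inversion in the test suite.  The feature Jacobian is
central finite differences with steps of $10^{-3}$ on the prior-whitened
scale (a Richardson test checks the $O(h^2)$ contract, and the backend is
pluggable).

**Error-precision structure.**  By default a *single* log-precision scales
one fixed precision component whose diagonal weights every feature by the
inverse squared per-frequency magnitude of the data CSD.  This is a
relative-error noise model, and it is the statistically appropriate one for
spectra: periodogram- and AR-derived estimates have standard errors
proportional to the spectrum itself, and resting-state CSDs span four to
five orders of magnitude across the band.  Under a uniform absolute
precision the largest (and noisiest) low-frequency bins dominate the fit;
in our recovery experiments that regime produced heavily shrunk, sometimes
sign-flipped connectivity estimates, while the relative weighting recovers
all four generative connections with typical error ~0.05 Hz.  A uniform
component remains one line of code away
(`hyperparameters(Q = list(rep(1, n)))`).  The hyperprior is
$\lambda \sim N(0, 1)$ — weak at these feature counts.

**Priors** (`default_prior()`): connections zero-mean with variance
$1/128$; log transit-time factors zero-mean with variance $1/256$; noise
log-amplitudes centered on the package defaults with variance $1/64$; the
spectral exponent $\beta$ fixed at 1.  Parameters are excluded from a model
by `exclude_parameter()` (mean and variance zero — the parameter is fixed
at zero and leaves the tunable subspace, contributing no KL term, which
also avoids a singular prior covariance) or frozen at a nonzero mean by
`set_tunable()`.  `compare_free_energies()` refuses to rank fits whose
data fingerprints differ, so free energies are only ever compared on
identical data.

# The synthetic-data generator

`simulate_bold()` is the package's reference data source and its own
validation instrument.  It integrates the *full nonlinear* model by
Euler–Maruyama at $\mathrm{d}t = 0.1$ s, driven by power-law state noise
synthesized spectrally (white Fourier coefficients scaled by
$\sqrt{S(f)}$, inverse transformed; seeded and exactly reproducible), takes
pointwise samples every TR — as an MR scanner does; there is no anti-alias
filter in the acquisition physics — adds power-law measurement noise
generated at the TR, and discards the first 32 s as a transient.

`default_scenario()` fixes the study conditions used throughout the tests:
three regions, generative connections $a_{12} = -0.2$, $a_{21} = 0.4$,
$a_{32} = -0.3$, $a_{23} = 0.2$, $a_{13} = a_{31} = 0$ (stored under the
target-row convention), hemodynamics at the defaults, TR = 2 s, 512
retained volumes.  The default noise amplitudes
($e^{\alpha_g} = e^{\alpha_r} = 3\times 10^{-6}$,
$e^{\alpha_m} = 10^{-6}$, $\beta = 1$) were calibrated once so that the
simulated BOLD standard deviation lies in the 0.1–1 percent range
(≈0.3 in practice) with in-band measurement noise well below the signal —
i.e. physiologically plausible resting-state data — and were not revisited.
The $1/f$ law is capped below one cycle per record length so that the
synthesis stays finite.

What the generator emulates: stationary endogenous fluctuations with $1/f$
structure, hemodynamic filtering, scanner-rate sampling, additive
measurement noise.  What it does not emulate: head motion, physiological
confounds (cardiac/respiratory), scanner drift beyond the power law,
spatial leakage between regions, and nonstationarity.  Passing recovery
tests therefore demonstrate internal consistency of the machinery on data
from its own model class — not robustness to the full complexity of
empirical fMRI.

# Validation results computed by the test suite

The statements below are exactly what `tests/testthat/` computes.

* **Connectivity recovery.** Simulate → estimate → invert over ten seeds
  recovers all four generative connections with correct signs in 10/10
  seeds; on the primary seed every posterior mean is within ±0.12 of its
  generative value (typically within ~0.05).
* **Model selection.** On the same ten seeds, the generative structure's
  free energy exceeds that of every model missing one of the strongly
  expressed connections ($a_{12}$, $a_{21}$, $a_{32}$) in 10/10 seeds, by
  tens to hundreds of nats, and the weakly expressed $a_{23}$ behaves as
  the most dispensable connection.  The fully connected over-complex model,
  however, overtakes the generative structure in about 4/10 seeds (by up to
  ~18 nats), although on average over seeds it does not win.  See
  *Limitations*.
* **Closed forms.** The scalar Ornstein–Uhlenbeck spectrum matches its
  Lorentzian to $10^{-8}$ relative; the matrix transfer function matches
  Simpson quadrature of the time-domain kernel to $10^{-6}$; the
  conjugate-Gaussian posterior and log evidence are reproduced to
  $10^{-6}$/$10^{-4}$.
* **Forward/backward spectral consistency.** The order-8 MVAR estimate of a
  long (4096-volume) simulation agrees with the linearized prediction at
  the generative parameters to roughly 25–30% in-band relative Frobenius
  error (close agreement in the mid-band diagonals, larger relative
  deviations at the band edges).

# Numerical choices and degenerate inputs

* State-Jacobian fallback and observation gradients: central differences,
  step $10^{-6}$ on the (order-1) state scale.
* Stability is checked from eigenvalues only (`eigen(only.values = TRUE)`);
  resolvent solves never require an eigenbasis.
* `fit_mvar` refuses fewer than $p \cdot n_{ch} + 2$ time points and
  rank-deficient lag designs; `mvar_csd` refuses nonstationary companion
  matrices (spectral radius ≥ 1) and grids beyond the Nyquist.
* Posterior covariances are formed by Cholesky inversion; a failed
  factorization inside a proposal rejects the step rather than aborting.
* Degenerate priors: zero-variance parameters are removed from the tunable
  subspace rather than carried with tiny variances.
* Ties/exact data: when the data equal the prediction exactly, the
  estimated log-precision saturates at its clamp (+32) and the posterior
  stays at the prior mean.

# Problem sizes

The shipped experiments are sized for a laptop-class single core: 512
volumes per scenario seed, ten seeds for recovery, six model structures ×
ten seeds for selection (~70 inversions; an inversion of the three-region
model takes well under a minute), and one 4096-volume run for the spectral
consistency check.

# Known limitations

* **Estimator realization error vs model comparison.** The ML (OLS) MVAR
  estimate is treated by the inversion as exact data.  Its realization
  error — and the residual systematic components discussed above (power
  below the analysis band entering through the AR poles, aliasing of
  above-Nyquist signal under pointwise sampling, Euler discretization) —
  is partly absorbed by whichever free parameters can fit it.  With 576
  highly redundant spectral features, sub-percent chance improvements in
  fit outweigh the ~2.5-nat complexity cost of an extra connection, so
  over-complex models can win model comparison on individual realizations
  even though they lose on average.  A shrinkage (Bayesian) AR estimator
  or an error model aware of the estimator's covariance would mitigate
  this; both are deliberate non-goals of the current version.
* **Linearization regime.** The CSD prediction is a first-order expansion
  at the resting fixed point; it degrades for large-amplitude fluctuations,
  and systems in limit cycles or other non-fixed-point regimes are out of
  scope.
* The generic model interface admits other region dynamics (any flow and
  observation with a fixed point at the origin), but only the linear
  neural mass + balloon model ships with analytic Jacobians and tested
  recovery.
* Field-strength presets are placeholders to be overridden with
  study-specific values; empirical fits require the acquisition TE.
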