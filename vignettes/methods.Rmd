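---
title: "Spectral DCM and hierarchical PEB for time-of-day effects: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral DCM and hierarchical PEB for time-of-day effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
generative model and its assumptions, the estimation machinery, the tunable
parameters with their defaults, what the synthetic cohorts do and do not
emulate, and the numerical choices made where the design was open.

## The generative model

Resting-state BOLD is modelled as the output of three coupled layers.

**Neuronal dynamics.** Regional activity `x` follows the linear stochastic
system `dx/dt = A x + v`. Off-diagonal entries of `A` are directed coupling
rates in Hz ("from columns to rows"); diagonal entries are parameterized on a
log scale, `A_ii = -0.5 * exp(a_ii)`, so the prior mean (`a_ii = 0`) is a
self-inhibition of −0.5 Hz and the sign is structurally negative. The
endogenous fluctuation `v` has a power-law spectral density
`g_v(f) = exp(alpha_v) * s0 * f^(-exp(beta_v))` shared across regions, with
`s0` a fixed amplitude constant (below) and the log-scale `alpha_v`,
`beta_v` centred on 0.

**Hemodynamics (Balloon model).** Per region: vasodilatory signal
`ds/dt = x - kappa s - gamma (f - 1)`, flow `df/dt = s`, venous volume
`tau dv/dt = f - v^(1/alpha_g)`, deoxyhemoglobin
`tau dq/dt = f E(f)/E0 - v^(1/alpha_g) q / v` with
`E(f) = 1 - (1 - E0)^(1/f)`. The free parameters are log-scale: the global
signal *decay* (`kappa = 0.64 exp(decay)` s⁻¹), per-region venous *transit*
(`tau = 2 exp(transit)` s), and *epsilon*, the intra/extravascular ratio in
the observer `y = V0 [k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)]` with
`k1 = 4.3 * 40.3 * E0 * TE`, `k2 = eps * 25 * E0 * TE`, `k3 = 1 - eps` at 3T
and TE = 33.1 ms. All fixed constants live in one table,
`balloon_constants()`: `gamma = 0.32`, `alpha_g = 0.32` (Grubb exponent),
`E0 = 0.4`, `V0 = 4`. These are the conventional defaults of the DCM
literature, treated as configuration, not as estimated quantities.

**Observation.** Measurement noise adds a second, independent power-law
spectrum (`alpha_e`, `beta_e`).

Linearizing about the resting fixpoint (x = s = 0, f = v = q = 1) yields the
transfer function `G(f) = L (2*pi*i*f*I - J)^(-1) B` and the predicted
cross-spectral density `S(f) = G g_v G* + g_e I` — a complex, Hermitian
ROI×ROI matrix per frequency. This is the quantity the inversion fits; the
analytic Jacobian of its feature vector with respect to all parameters is
implemented in compiled code and verified against central differences.

### The amplitude constant

The spectral amplitude constant is `s0 = 1/4096 * 1/16` (i.e. `amp_scale =
1/65536`). The constant is unit-free: observed series are rescaled to the
model's reference RMS (`reference_rms()`, the prior-mean model's in-band
amplitude) before inversion, so only ratios of data to model amplitude are
ever fit. The value is chosen so that *simulated* prior-mean fluctuations
keep the neuronal SD near 0.1 and hence the Balloon model in its
mildly-nonlinear regime: the flow responds to sustained activity with DC
gain `1/gamma ≈ 3`, so substantially larger neuronal excursions drive flow
and volume far from the fixpoint, where the simulator's own linearized
spectrum would no longer describe it. At the chosen scale the long-run Welch
spectrum of the nonlinear simulator matches the analytic spectrum to within
a few percent in band, which is what makes the simulator a valid oracle for
the estimation chain.

## Frequencies, features and data

The analysis band is the resting-state range: 32 linearly spaced frequencies
from `1/(n_volumes * TR)` to 0.1 Hz. Observed cross-spectra come from an
order-8 multivariate autoregression fitted by least squares (`fit_mar()`,
`mar_csd()`); a Welch segment-averaging estimator (`welch_csd()`, Hann
window, 50% overlap) serves as an independent oracle and is not used in
inversion. Spectra are mapped to a real feature vector (per frequency: real
parts of the Hermitian upper triangle, then imaginary parts of the strict
upper triangle; invertible round trip).

Features are pre-whitened by the prior-mean model's spectral scale at each
frequency (`csd_feature_weights()`). The sampling error of any spectral
estimate scales with the spectrum itself, so under a single noise precision
the unweighted low-frequency features (largest by a factor of ~50) would
dominate the fit; the weighting is equivalent to frequency-specific
precision blocks and markedly improves coupling recovery.

## Variational Laplace

`variational_laplace()` performs Gauss–Newton ascent on the Laplace free
energy with adaptive Levenberg–Marquardt damping: a proposed step is
accepted only if it increases the free energy; damping doubles on rejection
and halves on acceptance (bounds 1e-6 to 1e6, start 1e-2). A single log
noise precision over all features carries a Gaussian hyperprior (mean 4,
variance 16) and is re-optimized after every proposed step; setting its
prior precision to infinity fixes it, which is the conjugate test hook.
Convergence: free-energy improvement below 1e-2 on three consecutive
accepted steps, or 64 iterations. The posterior covariance is the inverse
curvature at the optimum, symmetrized with an eigenvalue floor of 1e-8. For
a linear forward map and fixed noise precision the free energy equals the
closed-form log marginal likelihood at the mode — asserted to 1e-6 in the
tests, which pins the implementation's constants (all 2*pi factors included).

A single initialization at the prior mean is used, as is conventional; no
restarts.

## Hierarchical PEB, model space, comparison

Subjects are allocated to six 2-hour timespans (09:00–21:00) by mid-scan
time; intervals are half-open with the final endpoint included, so a
boundary time such as 11:00 belongs to the later bin.

The 18 second-level design matrices have 12 rows — (timespan, session) cells
in timespan-major order, LR before RL, with identical rows for the two
sessions of a timespan so the sessions are averaged through the design — and
7 columns: the mean, the mean-centred time-effect column of the hypothesis,
and a 5-column sum-to-zero effects coding of the timespan factor. The
sinusoid family (models 12–17) evaluates one full cosine period over the six
bins at integer timespan indices, phase-shifted so model 12 peaks at
timespan 2; model 15 is then exactly the inverted waveform of model 12.
Every design has rank 6: the time column lies in the span of the mean plus
the timespan factor. Identification across models is therefore carried
entirely by the prior: each model places additional prior variance along its
own time-effect direction, and Bayesian model comparison asks which
direction the data's between-timespan structure actually follows.

`peb_fit()` estimates group effects from first-level posterior summaries
only: `theta_i = X_i beta + e_i`, `e_i ~ N(0, gamma * Sigma_prior / 16)`
with log-gamma optimized by (Laplace-corrected) marginal likelihood under a
N(0, 16) prior. Group effects have Gaussian priors of one prior-covariance
copy per design column, with a deliberate asymmetry: the mean and time
columns carry the full first-level prior covariance while the nuisance
timespan columns are shrunk 16-fold (`peb_config(beta_ratio = 1,
nuisance_ratio = 1/16)`). Without that asymmetry the effects-coded block —
which spans every possible between-timespan pattern — absorbs any genuine
diurnal profile and the null model always wins; with it, a model whose time
column matches the data explains the profile through one weakly-shrunk
direction while the null must pay the nuisance block's 16-fold quadratic
penalty. The ratio was calibrated once on posterior-level simulations
(detection of a decay profile vs. false selection on null data) and then
frozen.

The hierarchy (`hierarchical_peb()`) runs one mean-only PEB per (timespan,
session) cell — 12 fits — then one second-level PEB per design over the 12
cell posteriors. `bmc()` converts the 18 free energies to posterior model
probabilities by softmax under a uniform model prior. `bma()` moment-matches
the probability-weighted mixture of group posteriors, computes elementwise
posterior probabilities of nonzero effects by Bayesian model reduction
(collapsing each effect's prior variance to 1e-8; `pp = 1/(1 +
exp(delta_F))`) and blanks effects below pp 0.95 in the matrix renderings.
Per-timespan parameter profiles are reconstructed from the mean and time
columns only; the nuisance block parameterizes residual timespan variation
and is not part of the modelled diurnal profile.

Effect sizes follow the convention of reporting the selected model's
coefficients: `effect_size()` divides a model's time-effect posterior mean
by the between-subject SD of that parameter. The denominator is a
per-parameter 1-D optimization of the between-subject variance component
(the shared multi-parameter gamma would badly underestimate the dispersion
of a single parameter whose prior variance is small relative to the
others').

The analysis is run twice with different parameter selections: the full
A-matrix (`a_matrix_selection()`), and the hemodynamic set — per-ROI
transit, decay, epsilon, and the endogenous CSD amplitude/exponent pair
(`hemodynamic_selection()`).

## The synthetic cohorts

`cohort_config()` defaults encode the emulated study conditions: 8 ROIs
(the default-mode / salience / central-executive network of
`network_spec()`, 6 mm spheres), six timespans with group sizes
96/100/100/100/100/98, two sessions (LR/RL) per subject, TR 0.72 s, 1200
volumes (14.4 min), mid-scan times uniform within each 2-hour bin. All sizes
scale down for desk-scale work; the tests use 2–4 ROIs, 128–400 volumes and
8–32 subjects per timespan, and state those sizes explicitly.

Ground truth: off-diagonal couplings are drawn N(0, 0.2) truncated to ±0.5 Hz
with all other parameters at prior mean, resampled until every eigenvalue of
the effective `A` has real part below −0.2 (a stability margin; weakly
damped modes amplify the slow fluctuations beyond the Balloon model's mild
regime). Group-level time-of-day effects add `effect_size *
time_effect_column(model)[t]` to the chosen targets (decay, CSD amplitude,
transit, epsilon, or all off-diagonal couplings) on their native scales.
Subject-level variation perturbs every free parameter independently with SD
0.1 (the study's data carry no subject-level dispersion estimate; this is a
calibration choice, exposed in the config), redrawing until stable with
margin −0.1. The stability screen covers the full generative process: on
the rare draw (roughly one in several thousand at the default dispersion)
whose nonlinear integration still escapes the admissible regime, the cohort
generator rejects the draw and redraws that subject with a shifted seed.

Simulation synthesizes the endogenous input in the frequency domain
(amplitude `sqrt(g_v(f)/dt)` on white Gaussian noise — exact spectral
control, no autoregressive approximation), flattening the power law below
~0.001 Hz so the process variance stays finite over arbitrarily long runs
(real BOLD spectra flatten at ultradian frequencies too; the analysis band
is unaffected). States integrate with a fixed-step RK4 scheme at dt = TR/16,
with flow, volume and deoxyhemoglobin in log space so they remain positive;
64 burn-in volumes are discarded. Forward-Euler at this step size leaves a
~5% spectral bias, which RK4 removes. Measurement noise is added at volume
resolution; 12 motion-like confounds (six smoothed random walks plus
derivatives) and WM/CSF-like low-frequency regressors are generated with a
configurable leakage coefficient, 0 by default so preprocessing can be
tested on and off.

What the simulator does *not* emulate: scanner artifacts and k-space
effects, spatial structure beyond the small rendered test volumes, real
motion (the confounds are statistical stand-ins), aliased physiological
rhythms (cardiac/respiratory), chronotype or sleep covariates, and
between-site or between-day protocol differences. Passing tests therefore
show that the estimation chain is correct and well-calibrated *under the
generative model*, not that real resting-state data satisfy that model.

## Numerical choices and degenerate inputs

* Eigenvariates (first principal component, unit variance, sign fixed by
  positive mean loading) summarize ROI spheres, matching the originating
  software's convention; all-constant blocks are rejected.
* Sphere masks include voxels whose centers fall within the radius; the
  affine is authoritative (no orientation assumptions); 0-based indices.
* Nuisance regression projects out an intercept plus all confounds via QR
  and reports collinear columns by name.
* MAR fitting rejects ill-conditioned regressions with a suggestion to
  lower the order; order 0 is admitted and gives the flat spectrum
  `TR * Sigma`.
* BMR guards the reduced-posterior precision for positive definiteness and
  reports a conditioning failure rather than returning garbage.
* Non-finite second-level free energies are excluded from the softmax with
  a warning and the probabilities renormalized.
* All randomness is derived from integer seeds via a fixed 32-bit mixing
  function; cohort generation, inversion and the pipeline are deterministic
  given the configuration, and the RNG state of the caller is restored.

## Known limitations

* The inversion fits one noise precision over all (pre-whitened) features;
  strongly colored estimator error across ROI pairs is not modelled.
* Posterior shrinkage under the tight hemodynamic priors (variance 1/256)
  attenuates recovered decay/transit deviations by roughly half at
  desk-scale run lengths; model selection is robust to this, absolute
  effect magnitudes are not.
* Per-subject amplitude normalization is deliberately avoided in favor of a
  cohort-level constant; cohorts analyzed subject-by-subject with separate
  scales would partially absorb CSD-amplitude effects into the scale.
* The between-cell variance component at the second level is a single
  scaled copy of the prior covariance; structured session effects (LR vs RL
  biases) are absorbed by it rather than modelled explicitly.
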