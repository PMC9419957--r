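#' Hemodynamic and spectral constants
#'
#' One auditable table of the fixed constants of the Balloon observation
#' model and of the power-law innovation spectra. Values follow the
#' conventional 3T defaults of the DCM literature: vasodilatory signal decay
#' rate `kappa0` (s^-1), flow-dependent elimination `gamma` (s^-1), venous
#' transit time `tau0` (s), Grubb exponent `alpha_g`, resting oxygen
#' extraction `E0`, resting venous volume fraction `V0` (percent), echo time
#' `TE` (s), intravascular relaxation rate `r0` (s^-1), frequency offset
#' `theta0` (s^-1). The innovation spectra are
#' `g(f) = exp(alpha) * amp_scale * f^-exp(beta)` at the zero-centred
#' log-scale parameters; `amp_scale` is chosen so that prior-mean endogenous
#' fluctuations keep the Balloon nonlinearity in its mild regime (neuronal
#' SD ~0.1), and is unit-free because observed series are rescaled to the
#' model's reference RMS before inversion.
#'
#' @return Named list of constants.
#' @export
balloon_constants <- function() {
  list(kappa0 = 0.64, gamma = 0.32, tau0 = 2, alpha_g = 0.32,
       E0 = 0.4, V0 = 4, TE = 0.0331, r0 = 25, theta0 = 40.3,
       amp_scale = 1 / 65536, beta_prior = 1)
}

#' DCM parameter set
#'
#' Container for the parameters of the generative model: effective
#' connectivity `a` (an n x n matrix whose off-diagonal entries are coupling
#' rates in Hz and whose diagonal entries are log-scale self-connection
#' parameters, mapped to rates by [self_connection_rate()]), per-ROI log-scale
#' venous `transit` times, global log-scale `decay` and `epsilon`
#' (intra/extravascular ratio), and the log-scale amplitude/exponent pairs of
#' the endogenous-fluctuation (`alpha_v`, `beta_v`) and observation-noise
#' (`alpha_e`, `beta_e`) spectra. All log-scale parameters have prior mean 0.
#'
#' @param n_rois Number of regions.
#' @param a n x n matrix as described; default zero (prior mean).
#' @param transit Numeric n-vector, log scale.
#' @param decay,epsilon,alpha_v,beta_v,alpha_e,beta_e Scalars, log scale.
#' @return An object of class `dcm_params`.
#' @export
dcm_params <- function(n_rois, a = matrix(0, n_rois, n_rois),
                       transit = rep(0, n_rois), decay = 0, epsilon = 0,
                       alpha_v = 0, beta_v = 0, alpha_e = 0, beta_e = 0) {
  stopifnot(n_rois >= 1, is.matrix(a), all(dim(a) == n_rois),
            length(transit) == n_rois)
  structure(list(n_rois = as.integer(n_rois), a = a,
                 transit = as.numeric(transit),
                 decay = decay, epsilon = epsilon,
                 alpha_v = alpha_v, beta_v = beta_v,
                 alpha_e = alpha_e, beta_e = beta_e),
            class = "dcm_params")
}

param_names <- function(n_rois) {
  n <- n_rois
  an <- outer(seq_len(n), seq_len(n), function(i, j) sprintf("a[%d,%d]", i, j))
  c(as.vector(an), sprintf("transit[%d]", seq_len(n)),
    "decay", "epsilon", "alpha_v", "beta_v", "alpha_e", "beta_e")
}

#' Flatten / restore DCM parameters
#'
#' Canonical parameter ordering: the `a` matrix column-major (`a[i,j]` is the
#' influence of region j on region i, from columns to rows), then `transit`
#' per ROI, then `decay`, `epsilon`, `alpha_v`, `beta_v`, `alpha_e`, `beta_e`.
#'
#' @param params A [dcm_params()] object.
#' @return Named numeric vector of length `n^2 + n + 6`.
#' @export
pack_params <- function(params) {
  stopifnot(inherits(params, "dcm_params"))
  v <- c(as.vector(params$a), params$transit, params$decay, params$epsilon,
         params$alpha_v, params$beta_v, params$alpha_e, params$beta_e)
  names(v) <- param_names(params$n_rois)
  v
}

#' @rdname pack_params
#' @param theta Named numeric vector in canonical ordering.
#' @param n_rois Number of regions.
#' @export
unpack_params <- function(theta, n_rois) {
  n <- n_rois
  stopifnot(length(theta) == n^2 + n + 6)
  a <- matrix(theta[seq_len(n^2)], n, n)
  rest <- theta[-seq_len(n^2)]
  dcm_params(n, a = a, transit = rest[seq_len(n)],
             decay = rest[n + 1], epsilon = rest[n + 2],
             alpha_v = rest[n + 3], beta_v = rest[n + 4],
             alpha_e = rest[n + 5], beta_e = rest[n + 6])
}

#' Self-connection rate implied by a log-scale parameter
#'
#' Diagonal entries of the connectivity matrix are estimated on a log scale
#' relative to a prior mean rate of -0.5 Hz: the effective rate is
#' `-0.5 * exp(x)`, strictly negative for any finite `x`, which enforces
#' self-inhibition and hence stability pressure on the network.
#'
#' @param a_self Numeric vector of log-scale self-connection parameters.
#' @return Rates in Hz (negative).
#' @examples
#' self_connection_rate(0)      # -0.5 Hz, the prior mean
#' self_connection_rate(log(2)) # -1 Hz
#' @export
self_connection_rate <- function(a_self) {
  stopifnot(all(is.finite(a_self)))
  -0.5 * exp(a_self)
}

#' Effective connectivity matrix in Hz
#'
#' Combines off-diagonal couplings (Hz) with the scaled diagonal.
#' @param params A [dcm_params()] object.
#' @return n x n matrix of rates.
#' @export
effective_A <- function(params) {
  A <- params$a
  diag(A) <- self_connection_rate(diag(params$a))
  A
}

#' Power-law innovation spectrum
#'
#' Spectral density `g(f) = exp(alpha) * amp_scale * f^-(beta_prior*exp(beta))`
#' of the endogenous fluctuations or the observation noise, with the
#' log-scale amplitude/exponent parameterization of [balloon_constants()].
#'
#' @param alpha,beta Log-scale amplitude and exponent parameters.
#' @param freq Frequencies in Hz, strictly positive.
#' @return Nonnegative densities, one per frequency.
#' @export
innovation_spectrum <- function(alpha, beta, freq) {
  if (any(freq <= 0)) stop("`freq` must be strictly positive", call. = FALSE)
  cst <- balloon_constants()
  exp(alpha) * cst$amp_scale * freq^(-cst$beta_prior * exp(beta))
}

#' Frequency grid for spectral fitting
#'
#' @param n_volumes,TR Length and repetition time (s) of the series the grid
#'   will be compared to; the lowest frequency is `1/(n_volumes*TR)`.
#' @param n_freq Number of linearly spaced frequencies.
#' @param f_max Upper band edge in Hz (default 0.1 Hz, the resting-state
#'   fluctuation band); must not exceed the Nyquist frequency `1/(2*TR)`.
#' @return Numeric vector of ascending frequencies in Hz.
#' @export
frequency_grid <- function(n_volumes, TR, n_freq = 32, f_max = 0.1) {
  stopifnot(TR > 0, n_volumes > 1)
  if (f_max > 1 / (2 * TR))
    stop("`f_max` exceeds the Nyquist frequency", call. = FALSE)
  seq(1 / (n_volumes * TR), f_max, length.out = n_freq)
}

#' Jacobian of the linearized neuronal + Balloon system
#'
#' Linearizes the coupled system about its resting fixpoint
#' (x = s = 0, f = v = q = 1). Per region the hemodynamic states follow
#' ds/dt = x - kappa*s - gamma*(f-1), df/dt = s,
#' tau*dv/dt = f - v^(1/alpha_g), tau*dq/dt = f*E(f)/E0 - v^(1/alpha_g)*q/v
#' with E(f) = 1 - (1-E0)^(1/f), kappa = kappa0*exp(decay) and
#' tau = tau0*exp(transit_i). The BOLD observer is
#' y = V0*(k1*(1-q) + k2*(1-q/v) + k3*(1-v)) with epsilon entering k2, k3.
#' State ordering: all x, then s, f, v, q blocks (each per ROI).
#'
#' @param params A [dcm_params()] object.
#' @return List with `J` (5n x 5n), `B` (5n x n input map onto dx/dt) and
#'   `L` (n x 5n observation gradient).
#' @export
full_jacobian <- function(params) {
  th <- pack_params(params)
  if (!all(is.finite(th))) stop("non-finite parameters", call. = FALSE)
  n <- params$n_rois
  cst <- balloon_constants()
  kappa <- cst$kappa0 * exp(params$decay)
  tau <- cst$tau0 * exp(params$transit)
  eps <- exp(params$epsilon)
  E0 <- cst$E0; ag <- cst$alpha_g
  k1 <- 4.3 * cst$theta0 * E0 * cst$TE
  k2 <- eps * cst$r0 * E0 * cst$TE
  k3 <- 1 - eps

  ix <- seq_len(n); is <- n + ix; if_ <- 2 * n + ix
  iv <- 3 * n + ix; iq <- 4 * n + ix
  J <- matrix(0, 5 * n, 5 * n)
  J[ix, ix] <- effective_A(params)
  # dE/df at f = 1
  dEdf <- (1 - E0) * log(1 - E0)
  for (r in seq_len(n)) {
    J[is[r], ix[r]] <- 1
    J[is[r], is[r]] <- -kappa
    J[is[r], if_[r]] <- -cst$gamma
    J[if_[r], is[r]] <- 1
    J[iv[r], if_[r]] <- 1 / tau[r]
    J[iv[r], iv[r]] <- -1 / (ag * tau[r])
    J[iq[r], if_[r]] <- (E0 + dEdf) / (E0 * tau[r])
    J[iq[r], iv[r]] <- -(1 / ag - 1) / tau[r]
    J[iq[r], iq[r]] <- -1 / tau[r]
  }
  B <- matrix(0, 5 * n, n)
  B[ix, ] <- diag(n)
  L <- matrix(0, n, 5 * n)
  for (r in seq_len(n)) {
    L[r, iq[r]] <- -cst$V0 * (k1 + k2)
    L[r, iv[r]] <- cst$V0 * (k2 - k3)
  }
  list(J = J, B = B, L = L)
}

#' Nonlinear drift of the neuronal + Balloon system
#'
#' Time derivative of the full state (x, s, f, v, q per ROI) given neuronal
#' input `u`; used by the simulator and as the finite-difference oracle for
#' [full_jacobian()].
#'
#' @param state Numeric vector of length 5n, ordered as in [full_jacobian()].
#' @param params A [dcm_params()] object.
#' @param u Neuronal input vector (length n).
#' @return Derivative vector of length 5n.
#' @export
balloon_drift <- function(state, params, u = rep(0, params$n_rois)) {
  n <- params$n_rois
  cst <- balloon_constants()
  x <- state[seq_len(n)]; s <- state[n + seq_len(n)]
  f <- state[2 * n + seq_len(n)]; v <- state[3 * n + seq_len(n)]
  q <- state[4 * n + seq_len(n)]
  kappa <- cst$kappa0 * exp(params$decay)
  tau <- cst$tau0 * exp(params$transit)
  E <- 1 - (1 - cst$E0)^(1 / f)
  c(effective_A(params) %*% x + u,
    x - kappa * s - cst$gamma * (f - 1),
    s,
    (f - v^(1 / cst$alpha_g)) / tau,
    (f * E / cst$E0 - v^(1 / cst$alpha_g) * q / v) / tau)
}

#' BOLD observation of the Balloon states
#'
#' @inheritParams balloon_drift
#' @return Numeric n-vector of BOLD signal (percent-like units).
#' @export
bold_observe <- function(state, params) {
  n <- params$n_rois
  cst <- balloon_constants()
  v <- state[3 * n + seq_len(n)]; q <- state[4 * n + seq_len(n)]
  eps <- exp(params$epsilon)
  k1 <- 4.3 * cst$theta0 * cst$E0 * cst$TE
  k2 <- eps * cst$r0 * cst$E0 * cst$TE
  k3 <- 1 - eps
  cst$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Transfer function of the linearized generative model
#'
#' `G(2*pi*f) = L (i*2*pi*f*I - J)^-1 B`, the frequency response from
#' endogenous neuronal input to observed BOLD.
#'
#' @param params A [dcm_params()] object.
#' @param freq Frequencies in Hz.
#' @param jac Optional precomputed [full_jacobian()] result (test hook: pass a
#'   modified `L`/`B` to bypass hemodynamics).
#' @return Complex array `n x n x n_freq`.
#' @export
transfer_function <- function(params, freq, jac = full_jacobian(params)) {
  n <- params$n_rois
  m <- nrow(jac$J)
  G <- array(0i, c(n, n, length(freq)))
  for (k in seq_along(freq)) {
    w <- 2 * pi * freq[k]
    R <- solve(1i * w * diag(m) - jac$J, jac$B)
    G[, , k] <- jac$L %*% R
  }
  G
}

#' Predicted cross-spectral density
#'
#' The model cross-spectrum
#' `S(f) = G(f) g_v(f) G(f)^* + g_e(f) I`, with `g_v`, `g_e` the power-law
#' innovation and noise spectra of [innovation_spectrum()]. Hermitian with
#' nonnegative real diagonal at every frequency.
#'
#' @param params A [dcm_params()] object.
#' @param freq Frequencies in Hz.
#' @return An object of class `cross_spectrum`: list with `freq` and complex
#'   array `S` (n x n x n_freq).
#' @export
predict_csd <- function(params, freq) {
  n <- params$n_rois
  G <- transfer_function(params, freq)
  gv <- innovation_spectrum(params$alpha_v, params$beta_v, freq)
  ge <- innovation_spectrum(params$alpha_e, params$beta_e, freq)
  S <- array(0i, c(n, n, length(freq)))
  for (k in seq_along(freq)) {
    Gk <- G[, , k, drop = FALSE]; dim(Gk) <- c(n, n)
    Sk <- gv[k] * (Gk %*% Conj(t(Gk))) + ge[k] * diag(n)
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectrum(freq, S)
}

#' Cross-spectrum container
#'
#' @param freq Ascending positive frequencies (Hz).
#' @param S Complex array n x n x n_freq, Hermitian per frequency.
#' @return Object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(freq, S) {
  stopifnot(length(dim(S)) == 3, dim(S)[1] == dim(S)[2],
            dim(S)[3] == length(freq), all(freq > 0), !is.unsorted(freq))
  structure(list(freq = as.numeric(freq), S = S), class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("Cross-spectrum: %d x %d ROIs, %d frequencies in [%.4g, %.4g] Hz\n",
              dim(x$S)[1], dim(x$S)[2], length(x$freq),
              min(x$freq), max(x$freq)))
  invisible(x)
}
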