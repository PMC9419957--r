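#' Gaussian density container
#'
#' The unit passed up the PEB hierarchy: a multivariate Gaussian with named
#' dimensions.
#'
#' @param mean Numeric vector.
#' @param cov Symmetric PSD matrix (a scalar or vector is promoted to a
#'   diagonal).
#' @param names Optional dimension names (defaults to `names(mean)`).
#' @return Object of class `gaussian_density`.
#' @export
gaussian_density <- function(mean, cov, names = base::names(mean)) {
  force(names)
  mean <- as.numeric(mean)
  if (!is.matrix(cov)) cov <- diag(x = rep_len(as.numeric(cov), length(mean)),
                                   nrow = length(mean))
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("`cov` must be symmetric", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  structure(list(names = names, mean = stats::setNames(mean, names),
                 cov = cov), class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat(sprintf("Gaussian density over %d parameters\n", length(x$mean)))
  invisible(x)
}

#' Default priors for spectral DCM parameters
#'
#' Zero-mean shrinkage priors in the canonical ordering of [pack_params()]:
#' off-diagonal couplings and log-scale self-connections have variance 1/64
#' (so the implied prior self-connection rate is -0.5 Hz), the log-scale
#' hemodynamic parameters (transit, decay, epsilon) variance 1/256, and the
#' spectral amplitude/exponent parameters variance 1/64.
#'
#' @param n_rois Number of regions (>= 2).
#' @return A [gaussian_density()] over the packed parameter vector.
#' @export
default_priors <- function(n_rois) {
  stopifnot(n_rois >= 2)
  nm <- param_names(n_rois)
  v <- stats::setNames(numeric(length(nm)), nm)
  pv <- rep(1 / 64, length(nm))
  hemo <- grepl("^transit", nm) | nm %in% c("decay", "epsilon")
  pv[hemo] <- 1 / 256
  gaussian_density(v, diag(pv), names = nm)
}

#' Variational-Laplace configuration
#'
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Free-energy improvement below which a step counts towards
#'   convergence.
#' @param tol_streak Consecutive sub-`tol` accepted steps required.
#' @param damping Initial Levenberg-Marquardt damping.
#' @param damping_bounds Lower/upper damping bounds.
#' @param lambda0 Prior mean of the log noise precision.
#' @param lambda_prec Prior precision of the log noise precision; `Inf` fixes
#'   it at `lambda0` (the conjugate test hook).
#' @return List of class `vl_config`.
#' @export
vl_config <- function(max_iter = 64, tol = 1e-2, tol_streak = 3,
                      damping = 1e-2, damping_bounds = c(1e-6, 1e6),
                      lambda0 = 4, lambda_prec = 1 / 16) {
  structure(list(max_iter = max_iter, tol = tol, tol_streak = tol_streak,
                 damping = damping, damping_bounds = damping_bounds,
                 lambda0 = lambda0, lambda_prec = lambda_prec),
            class = "vl_config")
}

#' Frequency weights for cross-spectral features
#'
#' Spectral-estimator error is multiplicative (the sampling variance of a
#' cross-spectral estimate scales with the spectrum itself), so features are
#' pre-whitened by the prior-mean model's spectral scale at each frequency:
#' the weight is the reciprocal of the mean ROI spectral density of the
#' prior-mean model, replicated over the `n^2` features of that frequency.
#' Under a single noise precision this is equivalent to frequency-specific
#' precision blocks.
#'
#' @param n_rois Number of regions.
#' @param freq Frequency grid (Hz).
#' @return Numeric weight vector of length `length(freq) * n_rois^2`.
#' @export
csd_feature_weights <- function(n_rois, freq) {
  S0 <- predict_csd(dcm_params(n_rois), freq)
  sc <- vapply(seq_along(freq), function(k)
    mean(Re(diag(matrix(S0$S[, , k], n_rois, n_rois)))), numeric(1))
  rep(1 / sc, each = n_rois^2)
}

#' Forward map for cross-spectral inversion
#'
#' Returns a closure mapping a packed parameter vector to the predicted CSD
#' feature vector (and, on request, its analytic Jacobian) on a fixed grid,
#' optionally pre-whitened by [csd_feature_weights()]. Observed features
#' must be weighted identically.
#'
#' @param n_rois Number of regions.
#' @param freq Frequency grid (Hz).
#' @param weights Optional per-feature weight vector.
#' @return Function `f(theta, want_jacobian = FALSE)` returning a list with
#'   `features` and optionally `jacobian`.
#' @export
csd_forward <- function(n_rois, freq, weights = NULL) {
  force(n_rois); force(freq); force(weights)
  function(theta, want_jacobian = FALSE) {
    out <- csd_features_cpp(as.numeric(theta), n_rois, freq, want_jacobian)
    out$features <- as.numeric(out$features)
    if (!is.null(weights)) {
      out$features <- out$features * weights
      if (want_jacobian) out$jacobian <- out$jacobian * weights
    }
    out
  }
}

#' Laplace free energy of a parameter/hyperparameter setting
#'
#' The free-energy bound on log model evidence for a Gaussian observation
#' model with noise precision `exp(lambda)` on every feature: Gaussian
#' log-likelihood of the prediction error, Gaussian log-prior, and the
#' Laplace curvature (Occam) terms. For a linear forward map and fixed
#' `lambda` this is the exact log marginal likelihood at the posterior mode.
#'
#' @param theta Parameter vector.
#' @param features Observed feature vector.
#' @param priors A [gaussian_density()] over `theta`.
#' @param forward Forward map as returned by [csd_forward()].
#' @param lambda Log noise precision.
#' @param config A [vl_config()] (supplies the hyperprior).
#' @return Scalar free energy (nats).
#' @export
free_energy <- function(theta, features, priors, forward, lambda,
                        config = vl_config()) {
  fw <- forward(theta, want_jacobian = TRUE)
  vl_free_energy(theta, fw, features, priors, lambda, config)$F
}

# internal: free energy from a precomputed forward evaluation
vl_free_energy <- function(theta, fw, y, priors, lambda, config) {
  r <- y - fw$features
  J <- fw$jacobian
  N <- length(y)
  Pp <- chol2inv(chol(priors$cov))
  e <- theta - priors$mean
  Pe <- exp(lambda)
  H <- Pe * crossprod(J) + Pp
  ldPp <- determinant(Pp, logarithm = TRUE)$modulus
  cH <- tryCatch(chol(H), error = function(err) NULL)
  if (is.null(cH)) return(list(F = -Inf, H = H))
  ldH <- 2 * sum(log(diag(cH)))
  F <- -0.5 * Pe * sum(r^2) + 0.5 * N * lambda - 0.5 * N * log(2 * pi) -
    0.5 * sum(e * (Pp %*% e)) + 0.5 * as.numeric(ldPp) - 0.5 * ldH
  if (is.finite(config$lambda_prec)) {
    hl <- config$lambda_prec + 0.5 * Pe * sum(r^2)
    F <- F - 0.5 * config$lambda_prec * (lambda - config$lambda0)^2 +
      0.5 * log(config$lambda_prec) - 0.5 * log(hl)
  }
  list(F = F, H = H, r = r, J = J)
}

# internal: free energy from cached sufficient statistics
# (rr = r'r, JtJ = J'J, ee = e'Pp e, N = feature count)
vl_F_cached <- function(rr, JtJ, ee, N, Pp, ldPp, lambda, config) {
  Pe <- exp(lambda)
  H <- Pe * JtJ + Pp
  cH <- tryCatch(chol(H), error = function(err) NULL)
  if (is.null(cH)) return(-Inf)
  F <- -0.5 * Pe * rr + 0.5 * N * lambda - 0.5 * N * log(2 * pi) -
    0.5 * ee + 0.5 * ldPp - sum(log(diag(cH)))
  if (is.finite(config$lambda_prec)) {
    hl <- config$lambda_prec + 0.5 * Pe * rr
    F <- F - 0.5 * config$lambda_prec * (lambda - config$lambda0)^2 +
      0.5 * log(config$lambda_prec) - 0.5 * log(hl)
  }
  F
}

# internal: maximize free energy over lambda at fixed theta
vl_update_lambda <- function(rr, JtJ, ee, N, Pp, ldPp, lambda, config) {
  if (!is.finite(config$lambda_prec)) return(config$lambda0)
  stats::optimize(function(l) vl_F_cached(rr, JtJ, ee, N, Pp, ldPp, l, config),
                  interval = c(lambda - 8, lambda + 8),
                  maximum = TRUE, tol = 1e-3)$maximum
}

#' Variational-Laplace inversion
#'
#' Gauss-Newton ascent on the free energy with adaptive Levenberg-Marquardt
#' damping: a step is accepted only if it increases the free energy; damping
#' is doubled on rejection and halved on acceptance. The log noise precision
#' is re-optimized after every proposed parameter step. Deterministic given
#' inputs and configuration.
#'
#' @param features Observed feature vector.
#' @param priors A [gaussian_density()].
#' @param forward Forward map (see [csd_forward()]).
#' @param config A [vl_config()].
#' @return Object of class `inversion_result`: list with `posterior`
#'   (a [gaussian_density()]), `free_energy`, `lambda`, `iterations`,
#'   `converged`, `residual_norm`, `trace` (accepted free energies).
#' @export
variational_laplace <- function(features, priors, forward,
                                config = vl_config()) {
  theta <- priors$mean
  Pp <- chol2inv(chol(priors$cov))
  ldPp <- as.numeric(determinant(Pp, logarithm = TRUE)$modulus)
  N <- length(features)
  stats_of <- function(theta, fw) {
    r <- features - fw$features
    e <- theta - priors$mean
    list(r = r, J = fw$jacobian, rr = sum(r^2),
         JtJ = crossprod(fw$jacobian), Jtr = crossprod(fw$jacobian, r),
         ee = sum(e * (Pp %*% e)))
  }
  fw <- forward(theta, want_jacobian = TRUE)
  st <- stats_of(theta, fw)
  lambda <- vl_update_lambda(st$rr, st$JtJ, st$ee, N, Pp, ldPp,
                             config$lambda0, config)
  Fcur <- vl_F_cached(st$rr, st$JtJ, st$ee, N, Pp, ldPp, lambda, config)
  delta <- config$damping
  streak <- 0L; it <- 0L
  trace <- Fcur
  while (it < config$max_iter) {
    it <- it + 1L
    Pe <- exp(lambda)
    H <- Pe * st$JtJ + Pp
    g <- Pe * st$Jtr - Pp %*% (theta - priors$mean)
    Hd <- H + delta * diag(diag(H), nrow(H))
    step <- tryCatch(solve(Hd, g), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      theta_new <- theta + as.numeric(step)
      fw_new <- tryCatch(forward(theta_new, want_jacobian = TRUE),
                         error = function(e) NULL)
      if (!is.null(fw_new) && all(is.finite(fw_new$features))) {
        st_new <- stats_of(theta_new, fw_new)
        lam_new <- vl_update_lambda(st_new$rr, st_new$JtJ, st_new$ee, N, Pp,
                                    ldPp, lambda, config)
        Fcand <- vl_F_cached(st_new$rr, st_new$JtJ, st_new$ee, N, Pp, ldPp,
                             lam_new, config)
        if (is.finite(Fcand) && Fcand > Fcur) {
          accepted <- TRUE
          dF <- Fcand - Fcur
          theta <- theta_new; lambda <- lam_new; st <- st_new; Fcur <- Fcand
          trace <- c(trace, Fcand)
          delta <- max(delta / 2, config$damping_bounds[1])
          streak <- if (dF < config$tol) streak + 1L else 0L
          if (streak >= config$tol_streak) break
        }
      }
    }
    if (!accepted) {
      delta <- delta * 2
      if (delta > config$damping_bounds[2]) break
    }
  }
  Pe <- exp(lambda)
  H <- Pe * st$JtJ + Pp
  Sg <- chol2inv(chol((H + t(H)) / 2))
  # symmetrize and floor the spectrum for downstream PEB stability
  Sg <- (Sg + t(Sg)) / 2
  eg <- eigen(Sg, symmetric = TRUE)
  Sg <- eg$vectors %*% (pmax(eg$values, 1e-8) * t(eg$vectors))
  structure(list(
    posterior = gaussian_density(theta, Sg, names = priors$names),
    free_energy = Fcur, lambda = lambda, iterations = it,
    converged = streak >= config$tol_streak,
    residual_norm = sqrt(st$rr), trace = trace),
    class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "Spectral DCM inversion: F = %.2f, %d iterations (%sconverged)\n",
    x$free_energy, x$iterations, if (x$converged) "" else "not "))
  invisible(x)
}

#' Tidy an inversion result
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate`, `std.error`.
#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(parameter = x$posterior$names,
                 estimate = unname(x$posterior$mean),
                 std.error = sqrt(pmax(diag(x$posterior$cov), 0)))
}

#' @export
#' @rdname tidy.inversion_result
glance.inversion_result <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy, iterations = x$iterations,
                 converged = x$converged, residual_norm = x$residual_norm,
                 lambda = x$lambda)
}

#' Serialize an inversion result to JSON
#'
#' Writes names, posterior mean and covariance, free energy and diagnostics.
#'
#' @param x An `inversion_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_inversion_result <- function(x, path) {
  stopifnot(inherits(x, "inversion_result"))
  jsonlite::write_json(list(
    names = x$posterior$names,
    mean = unname(x$posterior$mean),
    cov = apply(x$posterior$cov, 1, as.numeric, simplify = FALSE),
    free_energy = x$free_energy, lambda = x$lambda,
    iterations = x$iterations, converged = x$converged,
    residual_norm = x$residual_norm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Invert one subject-session record
#'
#' Composition demean -> MAR fit -> MAR cross-spectrum -> feature vector ->
#' variational Laplace; run once per session.
#'
#' @param record One-row tibble (or list) with elements `series`
#'   (volumes x ROI matrix) and `TR`; as produced by [simulate_cohort()] or
#'   [extract_roi_series()].
#' @param priors Optional [gaussian_density()]; defaults to
#'   [default_priors()] for the record's ROI count.
#' @param freq Optional frequency grid; defaults to [frequency_grid()] for
#'   the record's length and TR.
#' @param mar_order MAR order for the data features.
#' @param config A [vl_config()].
#' @return An `inversion_result`.
#' @export
#' @param scale Amplitude rescaling applied to the demeaned series before
#'   spectral estimation (see [reference_rms()]); cohort-level workflows pass
#'   a shared constant via [invert_cohort()].
#' @param estimator Data-feature estimator: `"mar"` (the default) or
#'   `"welch"`.
invert_subject <- function(record, priors = NULL, freq = NULL, mar_order = 8,
                           config = vl_config(), scale = 1,
                           estimator = c("mar", "welch")) {
  estimator <- match.arg(estimator)
  series <- if (is.data.frame(record)) record$series[[1]] else record$series
  TR <- if (is.data.frame(record)) record$TR[[1]] else record$TR
  n <- ncol(series)
  if (is.null(freq)) freq <- frequency_grid(nrow(series), TR)
  if (is.null(priors)) priors <- default_priors(n)
  y <- standardize_series(series) * scale
  S <- estimate_csd(y, freq, TR, estimator, mar_order)
  w <- csd_feature_weights(n, freq)
  variational_laplace(feature_vector(S) * w, priors,
                      csd_forward(n, freq, weights = w), config)
}

# internal: dispatch the observed-CSD estimator; the welch path uses a
# full-length window so the grid's lowest frequency stays resolvable
estimate_csd <- function(y, freq, TR, estimator, mar_order) {
  if (estimator == "welch") welch_csd(y, freq, TR, window_length = nrow(y))
  else mar_csd(fit_mar(y, order = mar_order), freq, TR)
}
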