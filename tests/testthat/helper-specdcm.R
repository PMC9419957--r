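# shared fixtures, built in code

# a stable random parameter set away from the prior mean
stable_params <- function(n, seed, spread = 0.2) {
  set.seed(seed)
  repeat {
    a <- matrix(rnorm(n * n, 0, spread), n, n)
    diag(a) <- rnorm(n, 0, 0.1)
    p <- dcm_params(n, a = a, transit = rnorm(n, 0, 0.05),
                    decay = rnorm(1, 0, 0.05), epsilon = rnorm(1, 0, 0.05),
                    alpha_v = rnorm(1, 0, 0.1), beta_v = rnorm(1, 0, 0.1),
                    alpha_e = rnorm(1, 0, 0.1), beta_e = rnorm(1, 0, 0.1))
    if (max(Re(eigen(effective_A(p), only.values = TRUE)$values)) < -0.2)
      return(p)
  }
}

# linear-Gaussian toy problem with its conjugate closed forms
conjugate_toy <- function(seed = 42, N = 12, d = 3, noise_prec = 25,
                          prior_var = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(N * d), N, d)
  theta <- rnorm(d)
  y <- as.numeric(X %*% theta + rnorm(N, 0, 1 / sqrt(noise_prec)))
  P0 <- diag(1 / prior_var, d)
  Pn <- noise_prec * crossprod(X) + P0
  mn <- solve(Pn, noise_prec * crossprod(X, y))
  Cy <- X %*% diag(prior_var, d) %*% t(X) + diag(1 / noise_prec, N)
  lml <- as.numeric(-0.5 * N * log(2 * pi) -
                      0.5 * determinant(Cy, logarithm = TRUE)$modulus -
                      0.5 * t(y) %*% solve(Cy, y))
  list(X = X, y = y, d = d, N = N, noise_prec = noise_prec,
       prior = gaussian_density(rep(0, d), diag(prior_var, d),
                                names = paste0("p", seq_len(d))),
       post_mean = as.numeric(mn), post_cov = solve(Pn), log_evidence = lml,
       forward = function(theta, want_jacobian = FALSE)
         list(features = as.numeric(X %*% theta), jacobian = X))
}

# subject-level posterior cohorts for PEB-level simulations: draws parameter
# vectors around per-timespan group means and wraps them as tight Gaussian
# "first-level posteriors" (no fMRI simulation or inversion involved)
posterior_cohort <- function(seed, effect_model, effect_size, n_sub = 32,
                             subj_sd = 0.1, est_sd = 0.05, atten = 1,
                             n_rois = 4, target = "decay") {
  set.seed(seed)
  sel <- hemodynamic_selection(n_rois)
  p <- length(sel)
  col <- time_effect_column(effect_model) * effect_size
  rows <- list()
  for (t in 1:6) for (ss in c("LR", "RL")) {
    posts <- lapply(seq_len(n_sub), function(i) {
      th <- stats::setNames(rep(0, p), sel)
      th[target] <- col[t] + rnorm(1, 0, subj_sd)
      gaussian_density(atten * th + rnorm(p, 0, est_sd), diag(est_sd^2, p),
                       names = sel)
    })
    rows[[length(rows) + 1L]] <-
      tibble::tibble(timespan = t, session = ss, result = posts)
  }
  dplyr::bind_rows(rows)
}

hemodynamic_prior <- function(n_rois = 4) {
  pr <- default_priors(n_rois)
  sel <- match(hemodynamic_selection(n_rois), pr$names)
  gaussian_density(pr$mean[sel], pr$cov[sel, sel, drop = FALSE],
                   names = pr$names[sel])
}
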