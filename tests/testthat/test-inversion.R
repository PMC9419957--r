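test_that("default priors match the documented table", {
  pr <- default_priors(8)
  expect_length(pr$mean, 64 + 8 + 6)
  expect_equal(sum(grepl("^a\\[", pr$names)), 64)
  expect_true(all(pr$mean == 0))
  v <- diag(pr$cov)
  expect_true(all(v[grepl("^a\\[", pr$names)] == 1 / 64))
  expect_true(all(v[grepl("^transit|^decay$|^epsilon$", pr$names)] == 1 / 256))
  expect_true(all(v[grepl("alpha_|beta_", pr$names)] == 1 / 64))
  # the prior mean is an admissible (stable) parameter set with -0.5 Hz
  # self-connections
  p0 <- unpack_params(pr$mean, 8)
  expect_equal(diag(effective_A(p0)), rep(-0.5, 8))
  expect_lt(max(Re(eigen(full_jacobian(p0)$J, only.values = TRUE)$values)), 0)
})

test_that("variational Laplace is exact in the conjugate case", {
  toy <- conjugate_toy()
  cfg <- vl_config(lambda0 = log(toy$noise_prec), lambda_prec = Inf,
                   tol = 1e-8, max_iter = 50)
  res <- variational_laplace(toy$y, toy$prior, toy$forward, cfg)
  expect_lt(max(abs(res$posterior$mean - toy$post_mean)), 1e-6)
  expect_lt(max(abs(res$posterior$cov - toy$post_cov)), 1e-6)
  expect_lt(abs(res$free_energy - toy$log_evidence), 1e-6)
  # free_energy() agrees at the optimum
  F0 <- free_energy(res$posterior$mean, toy$y, toy$prior, toy$forward,
                    lambda = log(toy$noise_prec), config = cfg)
  expect_lt(abs(F0 - toy$log_evidence), 1e-6)
})

test_that("free energy behaves like a log evidence bound", {
  toy <- conjugate_toy(seed = 7)
  cfg <- vl_config(lambda0 = log(toy$noise_prec), lambda_prec = Inf)
  # at the prior mean with zero data the parameter prior terms vanish:
  # F reduces to the (constant) likelihood normalization terms
  F0 <- free_energy(rep(0, toy$d), rep(0, toy$N), toy$prior, toy$forward,
                    lambda = log(toy$noise_prec), config = cfg)
  Pp <- solve(toy$prior$cov)
  H <- toy$noise_prec * crossprod(toy$X) + Pp
  expect_equal(F0,
               0.5 * toy$N * log(toy$noise_prec) -
                 0.5 * toy$N * log(2 * pi) +
                 0.5 * determinant(Pp)$modulus -
                 0.5 * determinant(H)$modulus,
               tolerance = 1e-10, ignore_attr = TRUE)
  # corrupting the data lowers F at fixed parameters
  set.seed(1)
  F_clean <- free_energy(toy$post_mean, toy$y, toy$prior, toy$forward,
                         lambda = log(toy$noise_prec), config = cfg)
  F_noisy <- free_energy(toy$post_mean, toy$y + rnorm(toy$N, 0, 1),
                         toy$prior, toy$forward,
                         lambda = log(toy$noise_prec), config = cfg)
  expect_lt(F_noisy, F_clean)
})

test_that("accepted free-energy steps are monotone and deterministic", {
  p <- stable_params(3, seed = 13)
  f <- frequency_grid(400, 0.72, 16)
  y <- feature_vector(predict_csd(p, f))
  pr <- default_priors(3)
  r1 <- variational_laplace(y, pr, csd_forward(3, f), vl_config(max_iter = 30))
  r2 <- variational_laplace(y, pr, csd_forward(3, f), vl_config(max_iter = 30))
  expect_true(all(diff(r1$trace) > 0))
  expect_identical(r1$posterior$mean, r2$posterior$mean)
  expect_identical(r1$free_energy, r2$free_energy)
})

test_that("noise-free self-inversion recovers the coupling parameters", {
  p <- stable_params(3, seed = 7)
  f <- frequency_grid(400, 0.72, 32)
  w <- csd_feature_weights(3, f)
  y <- feature_vector(predict_csd(p, f)) * w
  res <- variational_laplace(y, default_priors(3),
                             csd_forward(3, f, weights = w),
                             vl_config(max_iter = 128, tol = 1e-4))
  th <- pack_params(p)
  est <- res$posterior$mean
  off <- intersect(grep("^a\\[", names(th)),
                   which(!names(th) %in% sprintf("a[%d,%d]", 1:3, 1:3)))
  rel <- abs(est[off] - th[off]) / pmax(abs(th[off]), 1e-6)
  expect_lt(max(rel), 0.05)
  # local optimality: jitters around the optimum do not improve F
  set.seed(2)
  fwd <- csd_forward(3, f, weights = w)
  for (i in 1:5) {
    jit <- est + rnorm(length(est), 0, 0.02)
    Fj <- free_energy(jit, y, default_priors(3), fwd, lambda = res$lambda,
                      config = vl_config())
    expect_lt(Fj, res$free_energy + 1e-6)
  }
})

test_that("subject inversion runs per session and recovers connectivity", {
  cfg <- cohort_config(n_rois = 4, n_subjects_per_timespan = 1,
                       n_volumes = 400, between_subject_sd = 0, seed = 11)
  tr <- make_ground_truth(cfg)
  th <- pack_params(tr$base_params)
  rows <- lapply(1:8, function(s) simulate_subject(tr, 1, "LR", s))
  cohort <- dplyr::bind_rows(rows)
  inv <- invert_cohort(cohort)
  expect_length(inv$result, 8)
  offd <- which(as.vector(outer(1:4, 1:4, `!=`)))
  cors <- vapply(inv$result, function(r)
    stats::cor(r$posterior$mean[offd], th[offd]), numeric(1))
  expect_gte(mean(cors), 0.7)
  # the two sessions of one subject yield two independent results
  r_lr <- invert_subject(simulate_subject(tr, 1, "LR", 99))
  r_rl <- invert_subject(simulate_subject(tr, 1, "RL", 99))
  expect_s3_class(r_lr, "inversion_result")
  expect_false(identical(r_lr$posterior$mean, r_rl$posterior$mean))
  # tidy/glance interfaces
  td <- tidy(r_lr)
  expect_identical(td$parameter, r_lr$posterior$names)
  expect_s3_class(glance(r_lr), "tbl_df")
})
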