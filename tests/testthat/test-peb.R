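test_that("Bayesian model reduction reproduces closed-form evidence changes", {
  set.seed(1)
  d <- 4
  # a fitted linear-Gaussian model to reduce
  X <- matrix(rnorm(20 * d), 20, d)
  y <- as.numeric(X %*% rnorm(d) + rnorm(20, 0, 0.3))
  Pe <- 1 / 0.3^2
  evidence_under <- function(S0) {
    Cy <- X %*% S0 %*% t(X) + diag(1 / Pe, 20)
    as.numeric(-0.5 * 20 * log(2 * pi) -
                 0.5 * determinant(Cy, logarithm = TRUE)$modulus -
                 0.5 * t(y) %*% solve(Cy, y))
  }
  S_full <- diag(0.6, d)
  P_post <- Pe * crossprod(X) + solve(S_full)
  post <- gaussian_density(solve(P_post, Pe * crossprod(X, y)),
                           solve(P_post))
  prior <- gaussian_density(rep(0, d), S_full)
  # identity reduction changes nothing
  same <- bmr(post, prior, prior)
  expect_equal(same$delta_F, 0, tolerance = 1e-10)
  expect_equal(same$reduced_posterior$mean, post$mean, tolerance = 1e-10)
  # against an explicit re-fit under the reduced prior
  S_red <- diag(c(0.6, 1e-6, 0.6, 0.05))
  red <- bmr(post, prior, gaussian_density(rep(0, d), S_red))
  expect_equal(red$delta_F, evidence_under(S_red) - evidence_under(S_full),
               tolerance = 1e-8)
  P_red <- Pe * crossprod(X) + solve(S_red)
  expect_equal(red$reduced_posterior$mean,
               as.numeric(solve(P_red, Pe * crossprod(X, y))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # shrinking one prior variance pulls that posterior mean monotonically to 0
  vars <- c(0.6, 0.1, 0.01, 1e-4, 1e-8)
  means <- vapply(vars, function(v) {
    Sr <- S_full; Sr[2, 2] <- v
    abs(bmr(post, prior, gaussian_density(rep(0, d), Sr))$reduced_posterior$mean[2])
  }, numeric(1))
  expect_true(all(diff(means) < 1e-12))
})

test_that("PEB pools first-level posteriors by precision", {
  prior <- gaussian_density(c(0, 0), diag(0.25, 2), names = c("u", "w"))
  # identical subjects: the group mean is the shared mean
  shared <- gaussian_density(c(0.21, -0.12), diag(1e-4, 2),
                             names = c("u", "w"))
  fit <- peb_fit(replicate(6, shared, simplify = FALSE), prior = prior)
  expect_equal(unname(fit$group_posterior$mean), c(0.21, -0.12),
               tolerance = 1e-3)
  # two subjects: between the two means, nearer the more precise one
  p1 <- gaussian_density(c(0.4, 0), diag(1e-4, 2), names = c("u", "w"))
  p2 <- gaussian_density(c(-0.2, 0), diag(1e-2, 2), names = c("u", "w"))
  fit2 <- peb_fit(list(p1, p2), prior = prior)
  m <- fit2$group_posterior$mean[1]
  expect_gt(m, -0.2); expect_lt(m, 0.4)
  expect_gt(m, 0.1)  # pulled towards the precise subject
  # posteriors must share names
  expect_error(peb_fit(list(p1, gaussian_density(0, 1, names = "z")),
                       prior = prior), "names")
})

test_that("mean-only designs beat random designs on null group data", {
  prior <- hemodynamic_prior(2)
  p <- length(prior$mean)
  wins <- 0L
  for (rep in 1:20) {
    set.seed(rep)
    posts <- lapply(1:12, function(i)
      gaussian_density(rnorm(p, 0, 0.03), diag(0.03^2, p),
                       names = prior$names))
    f_mean <- peb_fit(posts, prior = prior)$free_energy
    Xr <- cbind(mean = 1, junk = rnorm(12))
    f_rand <- peb_fit(posts, Xr, prior = prior)$free_energy
    wins <- wins + (f_mean > f_rand)
  }
  expect_gte(wins, 16)
})

test_that("the hierarchy yields 12 first-level and 18 second-level fits", {
  res <- posterior_cohort(1, effect_model = 18, effect_size = 0, n_sub = 6)
  hier <- hierarchical_peb(res, prior = hemodynamic_prior(4))
  expect_equal(nrow(hier$first_level), 12)
  expect_length(hier$second_level, 18)
  expect_identical(vapply(hier$second_level, `[[`, 1L, "model_id"), 1:18)
  # exchangeability: permuting subjects within a cell changes nothing
  res2 <- dplyr::arrange(res, dplyr::desc(dplyr::row_number()))
  hier2 <- hierarchical_peb(res2, prior = hemodynamic_prior(4))
  expect_equal(vapply(hier$second_level, `[[`, numeric(1), "free_energy"),
               vapply(hier2$second_level, `[[`, numeric(1), "free_energy"),
               tolerance = 1e-6)
  # a missing cell is rejected by name
  expect_error(hierarchical_peb(res[res$timespan != 3, ],
                                prior = hemodynamic_prior(4)),
               "timespan 3")
})

test_that("model comparison is a softmax over free energies", {
  mk <- function(F, id) structure(list(free_energy = F, model_id = id),
                                  class = "peb_result")
  eq <- bmc(lapply(1:18, function(i) mk(5, i)))
  expect_equal(eq$posterior_probs, rep(1 / 18, 18))
  two <- bmc(list(mk(0, 1), mk(-3, 2)))
  expect_equal(two$posterior_probs, c(0.9526, 0.0474), tolerance = 1e-3)
  expect_equal(two$winning_id, 1L)
  expect_equal(sum(two$posterior_probs), 1)
  expect_warning(out <- bmc(list(mk(0, 1), mk(NaN, 2), mk(-1, 3))),
                 "non-finite")
  expect_equal(sum(out$posterior_probs), 1)
  expect_equal(out$posterior_probs[2], 0)
})

test_that("model averaging collapses correctly and prunes effects", {
  res <- posterior_cohort(3, effect_model = 18, effect_size = 0, n_sub = 8)
  hier <- hierarchical_peb(res, prior = hemodynamic_prior(4))
  # degenerate weights: BMA equals the selected model's posterior
  probs <- rep(0, 18); probs[18] <- 1
  avg <- bma(hier, probs)
  expect_equal(avg$averaged_posterior$mean,
               hier$second_level[[18]]$group_posterior$mean)
  expect_equal(avg$averaged_posterior$cov,
               hier$second_level[[18]]$group_posterior$cov,
               tolerance = 1e-10)
  # model 18 has a zero time column: per-timespan means are constant
  expect_equal(apply(avg$per_timespan_means, 2, function(x) diff(range(x))),
               rep(0, ncol(avg$per_timespan_means)), ignore_attr = TRUE)
  expect_true(all(avg$pp >= 0 & avg$pp <= 1, na.rm = TRUE))
})

test_that("null cohorts rarely flag significant time effects", {
  hits <- 0L
  for (rep in 1:10) {
    res <- posterior_cohort(100 + rep, effect_model = 18, effect_size = 0,
                            n_sub = 16)
    hier <- hierarchical_peb(res, prior = hemodynamic_prior(4))
    avg <- bma(hier)
    time_pp <- avg$pp[startsWith(names(avg$pp), "time:")]
    hits <- hits + all(time_pp < 0.95, na.rm = TRUE)
  }
  expect_gte(hits, 8)
})

test_that("effect sizes are the time effect over the between-subject SD", {
  fit <- structure(list(
    group_posterior = gaussian_density(c(0.1, 0.5), diag(0.01, 2),
                                       names = c("time:decay", "time:epsilon")),
    between_cov = diag(c(4, 4))), class = "peb_result")
  expect_equal(effect_size(fit, "decay", between_sd = c(decay = 2)), 0.05)
  expect_equal(effect_size(fit, "epsilon", between_sd = c(epsilon = 2)), 0.25)
  zero <- fit
  zero$group_posterior$mean["time:decay"] <- 0
  expect_equal(effect_size(zero, "decay", between_sd = c(decay = 2)), 0)
  expect_error(effect_size(fit, "decay", between_sd = c(decay = 0)), "SD")
  # recovery of a standardized injected effect of 0.3 on synthetic cohorts:
  # d estimated from the generating design's second-level fit
  hits <- 0L
  for (rep in 1:10) {
    res <- posterior_cohort(200 + rep, effect_model = 7,
                            effect_size = 0.3 * 0.1, subj_sd = 0.1,
                            est_sd = 0.02, n_sub = 32)
    hier <- hierarchical_peb(res, prior = hemodynamic_prior(4))
    d <- effect_size(hier$second_level[[7]], "decay")
    hits <- hits + (d >= 0.15 && d <= 0.45)
  }
  expect_gte(hits, 8)
})
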