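#' Bayesian model reduction
#'
#' Closed-form change in log evidence and reduced posterior when the prior of
#' a fitted Gaussian model is replaced by a reduced prior, without re-fitting.
#' With posterior precision P, prior precision P0 and reduced prior precision
#' Pr, the reduced posterior precision is `Pq = P - P0 + Pr` and
#' `delta_F = 0.5*(logdet P + logdet Pr - logdet P0 - logdet Pq)
#'  + 0.5*(mq'Pq mq - mr'Pr mr - m'P m + m0'P0 m0)`.
#'
#' @param full_posterior,full_prior,reduced_prior [gaussian_density()] objects
#'   of matching dimension.
#' @return List with `delta_F` (log evidence of the reduced model minus the
#'   full model) and `reduced_posterior` (a [gaussian_density()]).
#' @export
bmr <- function(full_posterior, full_prior, reduced_prior) {
  stopifnot(length(full_posterior$mean) == length(full_prior$mean),
            length(full_prior$mean) == length(reduced_prior$mean))
  prec <- function(g) {
    out <- tryCatch(chol2inv(chol(g$cov)), error = function(e) NULL)
    if (is.null(out))
      stop("singular covariance in Bayesian model reduction; ",
           "condition number of the combination is too large", call. = FALSE)
    out
  }
  P <- prec(full_posterior); P0 <- prec(full_prior); Pr <- prec(reduced_prior)
  m <- full_posterior$mean; m0 <- full_prior$mean; mr <- reduced_prior$mean
  Pq <- P - P0 + Pr
  cPq <- tryCatch(chol(Pq), error = function(e)
    stop("reduced-posterior precision not positive definite; ",
         "the prior reduction is incompatible with the posterior",
         call. = FALSE))
  mq <- as.numeric(chol2inv(cPq) %*% (P %*% m - P0 %*% m0 + Pr %*% mr))
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  delta_F <- 0.5 * (ld(P) + ld(Pr) - ld(P0) - 2 * sum(log(diag(cPq)))) +
    0.5 * (sum(mq * (Pq %*% mq)) - sum(mr * (Pr %*% mr)) -
             sum(m * (P %*% m)) + sum(m0 * (P0 %*% m0)))
  list(delta_F = delta_F,
       reduced_posterior = gaussian_density(mq, chol2inv(cPq),
                                            names = full_posterior$names))
}

#' PEB configuration
#'
#' @param gamma_interval Search interval for the log between-subject variance
#'   scale.
#' @param gamma_prior_sd Prior SD of the log variance scale (prior mean 0).
#' @param beta_ratio Prior covariance of the mean and hypothesized
#'   time-effect columns, as a fraction of the first-level prior covariance.
#' @param nuisance_ratio Prior covariance fraction for all other design
#'   columns (the effects-coded timespan factor). Keeping this an order of
#'   magnitude tighter than `beta_ratio` prevents the unstructured timespan
#'   block from absorbing a genuine time-of-day profile, which is what lets
#'   Bayesian model comparison separate the 18 (mutually collinear) designs.
#' @return List of class `peb_config`.
#' @export
peb_config <- function(gamma_interval = c(-8, 8), gamma_prior_sd = 4,
                       beta_ratio = 1, nuisance_ratio = 1 / 16) {
  structure(list(gamma_interval = gamma_interval,
                 gamma_prior_sd = gamma_prior_sd, beta_ratio = beta_ratio,
                 nuisance_ratio = nuisance_ratio),
            class = "peb_config")
}

# internal scalar analogue of peb_fit's variance-component optimization:
# one parameter, mean-only design
optimize_gamma_scalar <- function(mi, si, pv, config) {
  obj <- function(lg) {
    Vi <- si + exp(lg) * pv / 16
    Pb <- 1 / (config$beta_ratio * pv) + sum(1 / Vi)
    b <- sum(mi / Vi)
    -0.5 * sum(log(2 * pi * Vi)) - 0.5 * sum(mi^2 / Vi) + 0.5 * b^2 / Pb -
      0.5 * log(config$beta_ratio * pv) - 0.5 * log(Pb) -
      0.5 * (lg / config$gamma_prior_sd)^2
  }
  exp(stats::optimize(obj, interval = config$gamma_interval,
                      maximum = TRUE, tol = 1e-4)$maximum)
}

#' Parametric empirical Bayes over first-level posteriors
#'
#' Fits the hierarchical model `theta_i = sum_c X[i,c] beta_c + e_i`,
#' `e_i ~ N(0, Sigma_b)`, using only the first-level posterior summaries
#' (means and covariances). The between-subject covariance is a single scaled
#' component `Sigma_b = gamma * prior_cov/16`, with `log gamma` optimized by
#' free energy (Laplace-corrected marginal likelihood plus a Gaussian prior
#' on `log gamma`). Group effects `beta` carry a Gaussian prior of covariance
#' `beta_ratio * prior_cov` per design column.
#'
#' @param posteriors List of [gaussian_density()] over the same named
#'   parameters (or a list of `inversion_result`s).
#' @param design Numeric matrix with one row per posterior (default: the
#'   mean-only column of ones).
#' @param prior First-level prior [gaussian_density()] for the selected
#'   parameters; supplies the covariance scale of both `Sigma_b` and the
#'   `beta` prior.
#' @param selection Optional character/integer subset of parameter names to
#'   model (default: all).
#' @param config A [peb_config()].
#' @return Object of class `peb_result`: `group_posterior` (a
#'   [gaussian_density()] over `column:parameter`), `free_energy`, `gamma`,
#'   `between_cov`, `design`, `parameter_names`, `column_names`, `level`.
#' @export
peb_fit <- function(posteriors, design = NULL, prior, selection = NULL,
                    config = peb_config()) {
  posteriors <- lapply(posteriors, function(p)
    if (inherits(p, "inversion_result")) p$posterior else p)
  stopifnot(length(posteriors) >= 1,
            all(vapply(posteriors, inherits, TRUE, "gaussian_density")))
  nm_all <- posteriors[[1]]$names
  for (p in posteriors)
    if (!identical(p$names, nm_all))
      stop("all posteriors must share parameter names", call. = FALSE)
  if (is.null(selection)) selection <- nm_all
  sel <- if (is.character(selection)) match(selection, nm_all) else selection
  if (anyNA(sel)) stop("unknown parameters in `selection`", call. = FALSE)
  nm <- nm_all[sel]
  N <- length(posteriors)
  if (is.null(design)) design <- matrix(1, N, 1,
                                        dimnames = list(NULL, "mean"))
  design <- as.matrix(design)
  if (nrow(design) != N)
    stop("rows of `design` must match the number of posteriors", call. = FALSE)
  if (ncol(design) > nrow(design))
    stop("design has more columns than rows", call. = FALSE)
  if (!all(is.finite(design)))
    stop("design contains non-finite entries", call. = FALSE)
  p <- length(sel)
  C <- ncol(design)
  cn <- colnames(design)
  if (is.null(cn)) cn <- paste0("c", seq_len(C))

  prior_sel <- match(nm, prior$names)
  if (anyNA(prior_sel)) stop("prior does not cover the selection", call. = FALSE)
  Sp <- prior$cov[prior_sel, prior_sel, drop = FALSE]
  mu <- lapply(posteriors, function(g) unname(g$mean[sel]))
  Sg <- lapply(posteriors, function(g) g$cov[sel, sel, drop = FALSE])

  # beta prior: block-diagonal, one scaled copy of the first-level prior
  # covariance per design column; nuisance columns are shrunk harder
  ratios <- ifelse(cn %in% c("mean", "time"), config$beta_ratio,
                   config$nuisance_ratio)
  S0 <- kronecker(diag(ratios, C), Sp)
  P0 <- chol2inv(chol(S0))
  b0 <- rep(0, C * p)

  logml <- function(lg) {
    Sb <- exp(lg) * Sp / 16
    quad <- 0; ldet <- 0
    Pb <- P0
    b <- b0
    for (i in seq_len(N)) {
      Vi <- Sg[[i]] + Sb
      cVi <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(cVi)) return(list(F = -Inf))
      Wi <- chol2inv(cVi)
      ldet <- ldet + 2 * sum(log(diag(cVi)))
      quad <- quad + sum(mu[[i]] * (Wi %*% mu[[i]]))
      xi <- design[i, ]
      Pb <- Pb + kronecker(tcrossprod(xi), Wi)
      b <- b + as.numeric(kronecker(xi, Wi %*% mu[[i]]))
    }
    cPb <- tryCatch(chol(Pb), error = function(e) NULL)
    if (is.null(cPb)) return(list(F = -Inf))
    mb <- as.numeric(chol2inv(cPb) %*% b)
    F <- -0.5 * N * p * log(2 * pi) - 0.5 * ldet - 0.5 * quad +
      0.5 * sum(b * mb) -
      0.5 * as.numeric(determinant(S0, logarithm = TRUE)$modulus) -
      0.5 * 2 * sum(log(diag(cPb))) -
      0.5 * (lg / config$gamma_prior_sd)^2 -
      0.5 * log(2 * pi * config$gamma_prior_sd^2)
    list(F = F, mb = mb, Sb_post = chol2inv(cPb))
  }
  opt <- stats::optimize(function(lg) logml(lg)$F,
                         interval = config$gamma_interval, maximum = TRUE,
                         tol = 1e-4)
  lg <- opt$maximum
  fit <- logml(lg)
  # Laplace correction over log gamma (numeric curvature)
  h <- 1e-3
  curv <- -(logml(lg + h)$F - 2 * fit$F + logml(lg - h)$F) / h^2
  lap <- if (is.finite(curv) && curv > 0) 0.5 * log(2 * pi / curv) else 0
  bn <- as.vector(outer(nm, cn, function(a, b) paste0(b, ":", a)))
  structure(list(
    group_posterior = gaussian_density(fit$mb, fit$Sb_post, names = bn),
    free_energy = fit$F + lap, gamma = exp(lg),
    between_cov = exp(lg) * Sp / 16,
    beta_prior = gaussian_density(b0, S0, names = bn),
    design = design, parameter_names = nm, column_names = cn,
    n_subjects = N, level = 1L, prior = prior, config = config),
    class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("PEB fit: %d units, %d parameters x %d design columns, F = %.2f\n",
              x$n_subjects, length(x$parameter_names),
              length(x$column_names), x$free_energy))
  invisible(x)
}

#' Tidy a PEB fit
#'
#' @param x A `peb_result`.
#' @param ... Unused.
#' @return Tibble with `column`, `parameter`, `estimate`, `std.error`.
#' @export
tidy.peb_result <- function(x, ...) {
  tibble::tibble(
    column = rep(x$column_names, each = length(x$parameter_names)),
    parameter = rep(x$parameter_names, length(x$column_names)),
    estimate = unname(x$group_posterior$mean),
    std.error = sqrt(pmax(diag(x$group_posterior$cov), 0)))
}

#' @export
#' @rdname tidy.peb_result
glance.peb_result <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy, gamma = x$gamma,
                 n_units = x$n_subjects,
                 n_parameters = length(x$parameter_names))
}

#' Hierarchical PEB over timespans, sessions and the model space
#'
#' First level: one mean-only PEB per (timespan, session) cell over that
#' cell's subject posteriors (12 fits for the 6 x 2 design). Second level:
#' one PEB per design of the 18-model space, treating the 12 first-level
#' group posteriors as data, with the sessions averaged through the shared
#' design rows.
#'
#' @param results Tibble with columns `timespan`, `session`, and `result`
#'   (list of `inversion_result` or [gaussian_density()]), e.g. from
#'   [invert_cohort()].
#' @param model_space An [enumerate_model_space()].
#' @param prior First-level prior [gaussian_density()].
#' @param selection Parameter subset to analyse (e.g. the A-matrix block or
#'   the hemodynamic set).
#' @param config A [peb_config()].
#' @return Object of class `peb_hierarchy`: `first_level` (tibble of 12
#'   `peb_result`s), `second_level` (list of 18 `peb_result`s),
#'   `between_subject_sd` (named vector, averaged over cells), `model_space`.
#' @export
hierarchical_peb <- function(results, model_space = enumerate_model_space(),
                             prior, selection = NULL, config = peb_config()) {
  stopifnot(all(c("timespan", "session", "result") %in% names(results)))
  sessions <- sort(unique(results$session))
  if (length(sessions) != 2L)
    stop("expected exactly 2 sessions", call. = FALSE)
  cells <- tidyr::expand_grid(timespan = 1:6, session = sessions)
  first <- purrr::pmap(cells, function(timespan, session) {
    sub <- results[results$timespan == timespan & results$session == session, ]
    if (nrow(sub) == 0)
      stop(sprintf("no subjects in cell (timespan %d, session %s)",
                   timespan, session), call. = FALSE)
    peb_fit(sub$result, design = NULL, prior = prior, selection = selection,
            config = config)
  })
  # cell posteriors become second-level data, ordered timespan-major LR first
  cell_posteriors <- lapply(first, function(fit) {
    gaussian_density(fit$group_posterior$mean, fit$group_posterior$cov,
                     names = fit$parameter_names)
  })
  # per-parameter between-subject SD: optimize the variance component for
  # each parameter alone (the effect-size denominator); scalar fast path
  pn1 <- first[[1]]$parameter_names
  posteriors_list <- lapply(results$result, function(p)
    if (inherits(p, "inversion_result")) p$posterior else p)
  cell_of <- match(paste(results$timespan, results$session),
                   paste(cells$timespan, cells$session))
  sdb <- vapply(pn1, function(pname) {
    j <- match(pname, posteriors_list[[1]]$names)
    mi <- vapply(posteriors_list, function(g) unname(g$mean[j]), numeric(1))
    si <- vapply(posteriors_list, function(g) g$cov[j, j], numeric(1))
    pv <- prior$cov[match(pname, prior$names), match(pname, prior$names)]
    gam_p <- vapply(seq_len(nrow(cells)), function(i) {
      sel <- cell_of == i
      optimize_gamma_scalar(mi[sel], si[sel], pv, config)
    }, numeric(1))
    sqrt(mean(gam_p) * pv / 16)
  }, numeric(1))
  prior2 <- {
    sel <- match(first[[1]]$parameter_names, prior$names)
    gaussian_density(prior$mean[sel], prior$cov[sel, sel, drop = FALSE],
                     names = first[[1]]$parameter_names)
  }
  second <- lapply(model_space$designs, function(d) {
    fit <- peb_fit(cell_posteriors, design = d$matrix, prior = prior2,
                   config = config)
    fit$level <- 2L
    fit$model_id <- d$model_id
    fit$time_column <- d$time_column
    attr(fit, "between_subject_sd") <- sdb
    fit
  })
  structure(list(first_level = dplyr::mutate(cells, fit = first),
                 second_level = second,
                 between_subject_sd = sdb,
                 model_space = model_space, prior = prior2),
            class = "peb_hierarchy")
}

#' @export
print.peb_hierarchy <- function(x, ...) {
  cat(sprintf("Hierarchical PEB: %d first-level cells, %d second-level designs\n",
              nrow(x$first_level), length(x$second_level)))
  invisible(x)
}

#' Bayesian model comparison over the design space
#'
#' Posterior model probabilities are the softmax of the second-level free
#' energies under a uniform model prior; the winning model is the argmax.
#' Models with non-finite free energy are excluded with a warning and the
#' probabilities renormalized.
#'
#' @param second_level List of second-level `peb_result`s (or a
#'   `peb_hierarchy`).
#' @return Object of class `bmc_result`: tibble-backed list with
#'   `free_energies`, `posterior_probs`, `winning_id`.
#' @export
bmc <- function(second_level) {
  if (inherits(second_level, "peb_hierarchy"))
    second_level <- second_level$second_level
  Fm <- vapply(second_level, function(x) x$free_energy, numeric(1))
  ids <- vapply(seq_along(second_level), function(i) {
    mid <- second_level[[i]]$model_id
    if (is.null(mid)) i else mid
  }, numeric(1))
  ok <- is.finite(Fm)
  if (!all(ok)) {
    warning("excluding models with non-finite free energy: ",
            paste(ids[!ok], collapse = ", "))
  }
  pr <- rep(0, length(Fm))
  Fs <- Fm[ok] - max(Fm[ok])
  pr[ok] <- exp(Fs) / sum(exp(Fs))
  structure(list(model_id = as.integer(ids), free_energies = Fm,
                 posterior_probs = pr,
                 winning_id = as.integer(ids[which.max(replace(Fm, !ok, -Inf))])),
            class = "bmc_result")
}

#' @export
print.bmc_result <- function(x, ...) {
  cat(sprintf("Bayesian model comparison over %d models: winner = model %d (pp = %.3f)\n",
              length(x$model_id), x$winning_id,
              x$posterior_probs[match(x$winning_id, x$model_id)]))
  invisible(x)
}

#' @export
tidy.bmc_result <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, free_energy = x$free_energies,
                 posterior_prob = x$posterior_probs)
}

#' Bayesian model averaging over the design space
#'
#' Probability-weighted (moment-matched) average of the second-level group
#' posteriors over all models. Elementwise posterior probabilities of a
#' nonzero effect are computed by Bayesian model reduction: each group
#' effect's prior variance is collapsed towards zero and
#' `pp = 1/(1 + exp(delta_F))`. Per-timespan parameter means are
#' reconstructed by applying each model's design to its group effects before
#' averaging.
#'
#' @param second_level List of second-level `peb_result`s or a
#'   `peb_hierarchy`.
#' @param probs Posterior model probabilities (e.g. from [bmc()]); defaults
#'   to [bmc()] of `second_level`.
#' @param threshold_pp Posterior-probability cutoff below which effects are
#'   reported as not significant (default 0.95).
#' @return Object of class `bma_result`: `averaged_posterior`,
#'   `per_timespan_means` (6 x parameters), `pp` (named vector),
#'   `significant` (logical), `threshold`, plus the probabilities used.
#' @export
bma <- function(second_level, probs = NULL, threshold_pp = 0.95) {
  hier <- NULL
  if (inherits(second_level, "peb_hierarchy")) {
    hier <- second_level
    second_level <- hier$second_level
  }
  if (is.null(probs)) probs <- bmc(second_level)$posterior_probs
  stopifnot(length(probs) == length(second_level))
  gp <- lapply(second_level, `[[`, "group_posterior")
  d <- length(gp[[1]]$mean)
  mu <- Reduce(`+`, Map(function(g, w) w * g$mean, gp, probs))
  S2 <- Reduce(`+`, Map(function(g, w) w * (g$cov + tcrossprod(g$mean)),
                        gp, probs)) - tcrossprod(mu)
  S2 <- (S2 + t(S2)) / 2
  avg <- gaussian_density(mu, S2, names = gp[[1]]$names)

  # per-timespan reconstruction through each model's mean and time columns
  # (the nuisance block parameterizes residual timespan variation and is not
  # part of the modelled time-of-day profile)
  pn <- second_level[[1]]$parameter_names
  p <- length(pn)
  per_ts <- Reduce(`+`, Map(function(fit, w) {
    keep <- fit$column_names %in% c("mean", "time")
    X6 <- fit$design[seq(1, 12, by = 2), keep, drop = FALSE]
    Bmat <- matrix(fit$group_posterior$mean, nrow = ncol(fit$design),
                   byrow = TRUE)[keep, , drop = FALSE]
    w * (X6 %*% Bmat)
  }, second_level, probs))
  dimnames(per_ts) <- list(paste0("t", 1:6), pn)

  # elementwise pp of nonzero effect via BMR pruning on the averaged posterior
  ref <- second_level[[which.max(probs)]]
  full_prior <- gaussian_density(rep(0, d), ref$beta_prior$cov,
                                 names = gp[[1]]$names)
  pp <- vapply(seq_len(d), function(j) {
    red <- full_prior
    red$cov[j, ] <- red$cov[, j] <- 0
    red$cov[j, j] <- 1e-8
    dF <- tryCatch(bmr(avg, full_prior, red)$delta_F,
                   error = function(e) NA_real_)
    if (!is.finite(dF)) return(NA_real_)
    1 / (1 + exp(dF))
  }, numeric(1))
  names(pp) <- gp[[1]]$names
  out <- structure(list(averaged_posterior = avg, per_timespan_means = per_ts,
                        pp = pp, significant = !is.na(pp) & pp > threshold_pp,
                        threshold = threshold_pp, probs = probs,
                        parameter_names = pn,
                        column_names = second_level[[1]]$column_names),
                   class = "bma_result")
  if (!is.null(hier))
    attr(out, "between_subject_sd") <- hier$between_subject_sd
  out
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("Bayesian model average over %d models: %d/%d effects with pp > %.2f\n",
              length(x$probs), sum(x$significant, na.rm = TRUE),
              length(x$significant), x$threshold))
  invisible(x)
}

#' Effect size of the time-of-day effect on one parameter
#'
#' Cohen's d: the absolute time-effect posterior mean divided by the
#' between-subject SD of that parameter (the square root of the optimized
#' between-subject variance component of the first-level PEBs).
#'
#' @param x A `bma_result` from a [hierarchical_peb()] flow, or a
#'   `peb_result` whose design has a `time` column.
#' @param parameter Parameter name (e.g. `"decay"` or `"alpha_v"`).
#' @param between_sd Optional named vector of between-subject SDs; defaults
#'   to the one carried by `x`.
#' @return Cohen's d (signed by the effect direction).
#' @export
effect_size <- function(x, parameter, between_sd = NULL) {
  if (is.null(between_sd)) between_sd <- attr(x, "between_subject_sd")
  if (inherits(x, "peb_result")) {
    est <- x$group_posterior$mean[paste0("time:", parameter)]
    if (is.null(between_sd)) between_sd <- sqrt(diag(x$between_cov))
  } else if (inherits(x, "bma_result")) {
    est <- x$averaged_posterior$mean[paste0("time:", parameter)]
  } else stop("unsupported object", call. = FALSE)
  if (is.na(est)) stop("no time effect for parameter ", parameter, call. = FALSE)
  sd_b <- between_sd[parameter]
  if (is.null(sd_b) || is.na(sd_b) || sd_b <= 0)
    stop("between-subject SD for ", parameter,
         " is zero or unavailable", call. = FALSE)
  as.numeric(est / sd_b)
}
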