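#' Synthetic cohort configuration
#'
#' Defines the study conditions the simulator emulates: six timespan groups,
#' two sessions (LR/RL phase encoding) per subject, TR 0.72 s and 14.4-min
#' runs (1200 volumes), with per-timespan group sizes matching the printed
#' cohort (96, 100, 100, 100, 100, 98). Group-level time-of-day effects are
#' injected on the chosen targets proportionally to the time-effect column of
#' `effect_model_id`.
#'
#' @param n_rois Number of regions (>= 2).
#' @param n_subjects_per_timespan Scalar or 6-vector of group sizes.
#' @param n_volumes Volumes per run.
#' @param TR Repetition time in seconds.
#' @param sessions Session labels.
#' @param effect_model_id Time-of-day model whose column scales the injected
#'   effect (18 = null).
#' @param effect_targets Character subset of
#'   `c("decay", "csd_amplitude", "transit", "epsilon", "A_offdiag")`.
#' @param effect_size Deviation per unit of the time-effect column, on the
#'   target's native (log or linear) scale.
#' @param alpha_v,beta_v,alpha_e,beta_e Log-scale spectral parameters of the
#'   endogenous fluctuations and the measurement noise (0 = prior mean).
#' @param noise_scale_v,noise_scale_e Linear multipliers on the two noise
#'   amplitudes (0 switches a source off; test hook).
#' @param between_subject_sd SD of the Gaussian subject-level perturbation
#'   applied to every free parameter.
#' @param confound_leakage Coefficient with which the synthetic confounds
#'   leak into the observed series (0 = pure-series mode).
#' @param burn_volumes Burn-in discarded before recording.
#' @param seed Integer seed; every draw derives from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_rois = 8,
                          n_subjects_per_timespan = c(96, 100, 100, 100, 100, 98),
                          n_volumes = 1200, TR = 0.72,
                          sessions = c("LR", "RL"),
                          effect_model_id = 18,
                          effect_targets = "decay",
                          effect_size = 0.3,
                          alpha_v = 0, beta_v = 0, alpha_e = 0, beta_e = 0,
                          noise_scale_v = 1, noise_scale_e = 1,
                          between_subject_sd = 0.1,
                          confound_leakage = 0,
                          burn_volumes = 64,
                          seed = 1L) {
  stopifnot(n_rois >= 2, n_volumes >= 128, TR > 0,
            effect_model_id %in% 1:18,
            all(effect_targets %in%
                  c("decay", "csd_amplitude", "transit", "epsilon", "A_offdiag")))
  n_sub <- rep_len(as.integer(n_subjects_per_timespan), 6L)
  structure(list(n_rois = as.integer(n_rois),
                 n_subjects_per_timespan = n_sub,
                 n_volumes = as.integer(n_volumes), TR = TR,
                 sessions = sessions,
                 effect_model_id = as.integer(effect_model_id),
                 effect_targets = effect_targets, effect_size = effect_size,
                 alpha_v = alpha_v, beta_v = beta_v,
                 alpha_e = alpha_e, beta_e = beta_e,
                 noise_scale_v = noise_scale_v, noise_scale_e = noise_scale_e,
                 between_subject_sd = between_subject_sd,
                 confound_leakage = confound_leakage,
                 burn_volumes = as.integer(burn_volumes),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic 32-bit seed mixing
mix_seed <- function(...) {
  x <- 0
  for (v in c(...)) x <- (x * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(x)
}

#' Ground-truth parameters of a synthetic cohort
#'
#' Draws a base parameter set (off-diagonal couplings with magnitude at most
#' 0.5 Hz, self-connections and hemodynamics at the prior mean), resampling
#' until the effective connectivity is stable, then derives the six
#' per-timespan parameter sets by adding `effect_size * column[t]` on each
#' effect target.
#'
#' @param config A [cohort_config()].
#' @param max_redraws Stability redraw budget.
#' @return Object of class `ground_truth`: list with `base_params`,
#'   `per_timespan_params` (list of 6), `effect_column`, `config`.
#' @export
make_ground_truth <- function(config, max_redraws = 100) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_rois
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(mix_seed(config$seed, 7741))
  base <- NULL
  for (k in seq_len(max_redraws)) {
    a <- matrix(pmin(pmax(stats::rnorm(n * n, 0, 0.2), -0.5), 0.5), n, n)
    diag(a) <- 0
    cand <- dcm_params(n, a = a,
                       alpha_v = config$alpha_v, beta_v = config$beta_v,
                       alpha_e = config$alpha_e, beta_e = config$beta_e)
    if (max(Re(eigen(effective_A(cand), only.values = TRUE)$values)) < -0.2) {
      base <- cand; break
    }
  }
  if (is.null(base))
    stop("could not draw a stable base connectivity in ", max_redraws,
         " attempts", call. = FALSE)
  col <- time_effect_column(config$effect_model_id)
  per <- lapply(seq_len(6L), function(t) {
    p <- base
    d <- config$effect_size * col[t]
    for (target in config$effect_targets) {
      if (target == "decay") p$decay <- p$decay + d
      if (target == "epsilon") p$epsilon <- p$epsilon + d
      if (target == "csd_amplitude") p$alpha_v <- p$alpha_v + d
      if (target == "transit") p$transit <- p$transit + d
      if (target == "A_offdiag") {
        off <- !diag(nrow(p$a))
        p$a[off] <- p$a[off] + d
      }
    }
    if (max(Re(eigen(effective_A(p), only.values = TRUE)$values)) >= 0)
      stop("per-timespan parameters violate stability; reduce `effect_size`",
           call. = FALSE)
    p
  })
  structure(list(base_params = base, per_timespan_params = per,
                 effect_column = col, config = config),
            class = "ground_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Power-law noise series
#'
#' Synthesizes stationary real series whose two-sided spectral density is
#' `exp(alpha) * amp_scale * f^-exp(beta)` by shaping white Gaussian noise in the
#' frequency domain (exact spectral control; the zero-frequency bin is
#' suppressed, so the series is mean-free by construction).
#'
#' The density is flattened below `f_floor` (default ~0.001 Hz, well below
#' the resting-state analysis band) so that the process variance stays finite
#' over arbitrarily long runs, mirroring the ultradian flattening of real
#' BOLD spectra.
#'
#' @param n Number of samples.
#' @param dt Sampling interval (s).
#' @param alpha,beta Log-scale amplitude and exponent.
#' @param n_series Number of independent columns.
#' @param scale Additional linear amplitude multiplier.
#' @param f_floor Frequency below which the density is held constant (Hz).
#' @return n x n_series matrix.
#' @export
powerlaw_noise <- function(n, dt, alpha, beta, n_series = 1, scale = 1,
                           f_floor = 1 / 1024) {
  if (scale == 0) return(matrix(0, n, n_series))
  fk <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) / (n * dt)
  H <- numeric(n)
  H[-1] <- sqrt(innovation_spectrum(alpha, beta, pmax(fk[-1], f_floor)) / dt)
  w <- matrix(stats::rnorm(n * n_series), n, n_series)
  X <- stats::mvfft(w) * H
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  out * scale
}

#' Simulate one subject-session BOLD run
#'
#' Integrates the neuronal states `dx/dt = A x + v` (with `v` a power-law
#' endogenous fluctuation process) and the Balloon states per ROI with a
#' fixed-step RK4 scheme at `dt = TR/16`, samples the BOLD observer at
#' volume times after burn-in, and adds power-law measurement noise and the
#' configured confound leakage. Deterministic given
#' `(config$seed, subject_seed, session)`.
#'
#' @param truth A [make_ground_truth()] result.
#' @param timespan Timespan index 1..6.
#' @param session Session label.
#' @param subject_seed Integer distinguishing subjects.
#' @param subject_params Optional [dcm_params()] overriding the subject-level
#'   draw (used to share one draw across a subject's sessions).
#' @return One-row tibble with `subject_id`, `timespan`, `session`,
#'   `mid_scan_time`, `TR`, `series`, `confounds` (list columns), and the
#'   subject parameters in `params`.
#' @export
simulate_subject <- function(truth, timespan, session, subject_seed,
                             subject_params = NULL) {
  stopifnot(inherits(truth, "ground_truth"), timespan %in% 1:6)
  cfg <- truth$config
  n <- cfg$n_rois
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  if (is.null(subject_params)) {
    set.seed(mix_seed(cfg$seed, subject_seed, 11))
    subject_params <- draw_subject_params(truth$per_timespan_params[[timespan]],
                                          cfg$between_subject_sd)
  }
  set.seed(mix_seed(cfg$seed, subject_seed, match(session, cfg$sessions), 13))
  mid_scan <- stats::runif(1, 9 + 2 * (timespan - 1), 9 + 2 * timespan)

  sub <- 16L
  dt <- cfg$TR / sub
  steps <- (cfg$burn_volumes + cfg$n_volumes) * sub
  v_in <- powerlaw_noise(steps, dt, subject_params$alpha_v,
                         subject_params$beta_v, n, scale = cfg$noise_scale_v)
  cst <- balloon_constants()
  bold <- simulate_balloon_cpp(
    effective_A(subject_params), cst$tau0 * exp(subject_params$transit),
    cst$kappa0 * exp(subject_params$decay), exp(subject_params$epsilon),
    v_in, dt, sub, cfg$burn_volumes * sub, cfg$n_volumes)
  noise <- powerlaw_noise(cfg$n_volumes, cfg$TR, subject_params$alpha_e,
                          subject_params$beta_e, n, scale = cfg$noise_scale_e)
  series <- bold + noise
  conf <- make_confounds(cfg$n_volumes, cfg$TR)
  if (cfg$confound_leakage != 0) {
    W <- matrix(stats::rnorm(ncol(conf) * n, 0, 1), ncol(conf), n)
    series <- series + cfg$confound_leakage * (conf %*% W)
  }
  if (anyNA(series))
    stop("integration produced missing values for subject seed ",
         subject_seed, call. = FALSE)
  tibble::tibble(subject_id = sprintf("s%03d", subject_seed),
                 timespan = as.integer(timespan), session = session,
                 mid_scan_time = mid_scan, TR = cfg$TR,
                 series = list(series), confounds = list(conf),
                 params = list(subject_params))
}

draw_subject_params <- function(group_params, sd, max_redraws = 50) {
  if (sd == 0) return(group_params)
  th <- pack_params(group_params)
  n <- group_params$n_rois
  for (k in seq_len(max_redraws)) {
    cand <- unpack_params(th + stats::rnorm(length(th), 0, sd), n)
    if (max(Re(eigen(effective_A(cand), only.values = TRUE)$values)) < -0.1)
      return(cand)
  }
  stop("could not draw stable subject-level parameters", call. = FALSE)
}

# 12 motion-like regressors (6 smoothed random walks + their derivatives)
# plus WM-like and CSF-like low-frequency noise
make_confounds <- function(n_volumes, TR) {
  rw <- sapply(1:6, function(i)
    stats::filter(cumsum(stats::rnorm(n_volumes, 0, 0.02)),
                  rep(1 / 8, 8), sides = 1))
  rw[is.na(rw)] <- 0
  drw <- rbind(0, diff(rw))
  lf <- powerlaw_noise(n_volumes, TR, alpha = 0, beta = 0.5, n_series = 2)
  conf <- cbind(rw, drw, lf)
  colnames(conf) <- c(paste0("motion", 1:6), paste0("motion_d", 1:6),
                      "WM", "CSF")
  conf
}

#' Simulate a full multi-subject, multi-session cohort
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject-session (see
#'   [simulate_subject()]); the [make_ground_truth()] object is attached as
#'   attribute `"ground_truth"`.
#' @examples
#' cfg <- cohort_config(n_rois = 2, n_subjects_per_timespan = 1,
#'                      n_volumes = 128, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort)  # 1 x 6 x 2
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- make_ground_truth(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- list()
  sid <- 0L
  for (t in seq_len(6L)) {
    for (s in seq_len(config$n_subjects_per_timespan[t])) {
      sid <- sid + 1L
      # stability screening covers the full generative process: a draw whose
      # nonlinear integration blows up is rejected and redrawn (seeded)
      recs <- NULL
      for (try in seq_len(20L)) {
        set.seed(mix_seed(config$seed, sid, 11, try - 1L))
        sp <- draw_subject_params(truth$per_timespan_params[[t]],
                                  config$between_subject_sd)
        recs <- tryCatch(
          lapply(config$sessions, function(sess)
            simulate_subject(truth, t, sess, sid, subject_params = sp)),
          error = function(e) NULL)
        if (!is.null(recs)) break
      }
      if (is.null(recs))
        stop("could not simulate a stable subject for timespan ", t,
             call. = FALSE)
      rows <- c(rows, recs)
    }
  }
  out <- dplyr::bind_rows(rows)
  # one mid-scan time per subject, shared across sessions
  out <- out |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(mid_scan_time = dplyr::first(.data$mid_scan_time)) |>
    dplyr::ungroup()
  attr(out, "ground_truth") <- truth
  out
}

#' Write a cohort to delimited text plus a JSON manifest
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_len(nrow(cohort)), function(i) {
    fn <- sprintf("%s_%s.tsv", cohort$subject_id[i], cohort$session[i])
    utils::write.table(cohort$series[[i]], file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
    list(subject = cohort$subject_id[i], timespan = cohort$timespan[i],
         session = cohort$session[i],
         mid_scan_time = cohort$mid_scan_time[i], file = fn)
  })
  truth <- attr(cohort, "ground_truth")
  if (!is.null(truth))
    jsonlite::write_json(
      list(base_params = as.list(pack_params(truth$base_params)),
           effect_column = truth$effect_column),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
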