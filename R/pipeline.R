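#' Parameter subsets for the two group analyses
#'
#' The connectivity analysis covers the full A-matrix (n x n couplings
#' including the log-scale self-connections); the hemodynamic analysis covers
#' the per-ROI transit times, the global decay and epsilon, and the
#' endogenous CSD amplitude/exponent pair (alpha, beta).
#'
#' @param n_rois Number of regions.
#' @return Character vector of parameter names.
#' @export
a_matrix_selection <- function(n_rois) {
  nm <- param_names(n_rois)
  nm[grepl("^a\\[", nm)]
}

#' @rdname a_matrix_selection
#' @export
hemodynamic_selection <- function(n_rois) {
  nm <- param_names(n_rois)
  c(nm[grepl("^transit\\[", nm)], "decay", "epsilon", "alpha_v", "beta_v")
}

#' Model-implied reference RMS of a BOLD series
#'
#' Root-mean-square amplitude the generative model predicts at prior-mean
#' parameters for a series of the given sampling rate: the integral of the
#' mean ROI spectral density over the resolvable band. Used to rescale
#' observed series to the amplitude scale the priors expect (BOLD units are
#' arbitrary).
#'
#' @param n_rois Number of regions.
#' @param TR Repetition time (s).
#' @param f_floor Lower integration edge (Hz).
#' @return Scalar RMS.
#' @export
reference_rms <- function(n_rois, TR, f_floor = 1 / 1024) {
  f <- exp(seq(log(f_floor), log(1 / (2 * TR)), length.out = 256))
  S <- predict_csd(dcm_params(n_rois), f)
  dens <- vapply(seq_along(f), function(k)
    mean(Re(diag(matrix(S$S[, , k], n_rois, n_rois)))), numeric(1))
  # two-sided density integrated over positive frequencies
  sqrt(2 * sum(diff(f) * (dens[-1] + dens[-length(f)]) / 2))
}

#' Invert every subject-session record of a cohort
#'
#' Applies a common amplitude normalization (all series scaled by
#' `reference_rms / cohort RMS`, preserving between-subject amplitude
#' differences), then runs [invert_subject()] per record.
#'
#' @param cohort Tibble from [simulate_cohort()] (or with the same columns).
#' @param priors Optional [gaussian_density()]; defaults to
#'   [default_priors()].
#' @param freq Optional frequency grid.
#' @param mar_order MAR order for the data features.
#' @param config A [vl_config()].
#' @param normalize Logical; apply the cohort-level rescaling (default TRUE).
#' @param estimator Data-feature estimator, `"mar"` or `"welch"`.
#' @param progress Print one line per subject (default FALSE).
#' @return The cohort tibble with a `result` list-column of
#'   `inversion_result`s (series/confounds columns dropped).
#' @export
invert_cohort <- function(cohort, priors = NULL, freq = NULL, mar_order = 8,
                          config = vl_config(), normalize = TRUE,
                          estimator = c("mar", "welch"),
                          progress = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(nrow(cohort) >= 1)
  n <- ncol(cohort$series[[1]])
  TR <- cohort$TR[[1]]
  if (is.null(freq)) freq <- frequency_grid(nrow(cohort$series[[1]]), TR)
  if (is.null(priors)) priors <- default_priors(n)
  scale <- 1
  if (normalize) {
    rms <- sqrt(mean(vapply(cohort$series, function(s)
      mean(sweep(s, 2, colMeans(s))^2), numeric(1))))
    if (rms > 0) scale <- reference_rms(n, TR) / rms
  }
  w <- csd_feature_weights(n, freq)
  fwd <- csd_forward(n, freq, weights = w)
  results <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    y <- standardize_series(cohort$series[[i]]) * scale
    S <- estimate_csd(y, freq, TR, estimator, mar_order)
    results[[i]] <- variational_laplace(feature_vector(S) * w, priors, fwd,
                                        config)
    if (progress)
      message(sprintf("inverted %s/%s (%d/%d), F = %.1f",
                      cohort$subject_id[i], cohort$session[i], i,
                      nrow(cohort), results[[i]]$free_energy))
  }
  out <- dplyr::select(cohort, -dplyr::any_of(c("series", "confounds")))
  out$result <- results
  attr(out, "normalization_scale") <- scale
  out
}

#' Run the full simulate -> invert -> PEB -> BMC/BMA pipeline
#'
#' Executes the complete analysis on a synthetic cohort: cohort simulation,
#' (optional) nuisance regression, per-session spectral DCM inversion, the
#' hierarchical PEB over 6 timespans x 2 sessions, and Bayesian model
#' comparison plus averaging over the 18-design space, separately for the
#' connectivity (A-matrix) and hemodynamic parameter sets.
#'
#' @param config A [cohort_config()].
#' @param model_space An [enumerate_model_space()].
#' @param vl A [vl_config()].
#' @param peb A [peb_config()].
#' @param mar_order MAR order for the data features.
#' @param regress_confounds Run [nuisance_regress()] on each record first
#'   (default: TRUE when `config$confound_leakage != 0`).
#' @param progress Verbose per-subject logging.
#' @return Object of class `tod_report`: list with the inverted cohort, the
#'   two `peb_hierarchy` objects, `bmc` and `bma` per analysis, effect sizes
#'   for the hemodynamic analysis, stage wall-clock times and the
#'   configuration.
#' @export
run_pipeline <- function(config = cohort_config(), model_space = enumerate_model_space(),
                         vl = vl_config(), peb = peb_config(), mar_order = 8,
                         regress_confounds = config$confound_leakage != 0,
                         progress = FALSE) {
  timing <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  cohort <- simulate_cohort(config)
  timing["simulate"] <- toc(t0)

  if (regress_confounds) {
    t0 <- tic()
    cohort$series <- purrr::map2(cohort$series, cohort$confounds,
                                 nuisance_regress)
    timing["preprocess"] <- toc(t0)
  }

  t0 <- tic()
  priors <- default_priors(config$n_rois)
  inverted <- invert_cohort(cohort, priors = priors, mar_order = mar_order,
                            config = vl, progress = progress)
  timing["invert"] <- toc(t0)

  analyses <- list(connectivity = a_matrix_selection(config$n_rois),
                   hemodynamic = hemodynamic_selection(config$n_rois))
  out <- list()
  for (nm in names(analyses)) {
    t0 <- tic()
    hier <- hierarchical_peb(inverted, model_space, prior = priors,
                             selection = analyses[[nm]], config = peb)
    cmp <- bmc(hier)
    avg <- bma(hier, cmp$posterior_probs)
    out[[nm]] <- list(hierarchy = hier, bmc = cmp, bma = avg)
    timing[paste0("peb_", nm)] <- toc(t0)
  }
  # effect sizes from the winning hemodynamic model's time effect
  win_fit <- out$hemodynamic$hierarchy$second_level[[
    match(out$hemodynamic$bmc$winning_id,
          vapply(out$hemodynamic$hierarchy$second_level, `[[`, 1L,
                 "model_id"))]]
  es <- tryCatch(
    stats::setNames(
      vapply(c("decay", "alpha_v"), function(pnm)
        effect_size(win_fit, pnm), numeric(1)),
      c("decay", "alpha_v")),
    error = function(e) NULL)

  structure(list(cohort = inverted, connectivity = out$connectivity,
                 hemodynamic = out$hemodynamic, effect_sizes = es,
                 timing = timing, config = config,
                 ground_truth = attr(cohort, "ground_truth")),
            class = "tod_report")
}

#' @export
print.tod_report <- function(x, ...) {
  cat("Time-of-day spectral DCM report\n")
  cat(sprintf("  cohort: %d records, %d ROIs\n", nrow(x$cohort),
              x$config$n_rois))
  cat(sprintf("  connectivity analysis: winning model %d\n",
              x$connectivity$bmc$winning_id))
  cat(sprintf("  hemodynamic analysis:  winning model %d\n",
              x$hemodynamic$bmc$winning_id))
  if (!is.null(x$effect_sizes))
    cat(sprintf("  effect sizes: decay d = %.2f, CSD amplitude d = %.2f\n",
                x$effect_sizes["decay"], x$effect_sizes["alpha_v"]))
  invisible(x)
}

#' @export
glance.tod_report <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$cohort), n_rois = x$config$n_rois,
    winning_connectivity = x$connectivity$bmc$winning_id,
    winning_hemodynamic = x$hemodynamic$bmc$winning_id,
    effect_decay = if (is.null(x$effect_sizes)) NA_real_ else x$effect_sizes["decay"],
    effect_csd_amplitude = if (is.null(x$effect_sizes)) NA_real_ else x$effect_sizes["alpha_v"])
}

#' Render the group connectivity matrix with sub-threshold entries blanked
#'
#' ROI x ROI table of the averaged mean-column effects, from-columns-to-rows
#' by default. Diagonal entries are reported in Hz after the
#' [self_connection_rate()] mapping; entries whose posterior probability of
#' being nonzero falls below the threshold are blank.
#'
#' @param bma_conn A `bma_result` from the connectivity analysis.
#' @param threshold Posterior-probability cutoff (defaults to the one stored
#'   in `bma_conn`).
#' @param roi_names Optional ROI names.
#' @param from_columns_to_rows Orientation flag; `FALSE` transposes.
#' @param digits Rounding for display.
#' @return Character matrix; blanks mark non-significant effects.
#' @export
render_connectivity_matrix <- function(bma_conn, threshold = NULL,
                                       roi_names = NULL,
                                       from_columns_to_rows = TRUE,
                                       digits = 3) {
  stopifnot(inherits(bma_conn, "bma_result"))
  if (is.null(threshold)) threshold <- bma_conn$threshold
  pn <- bma_conn$parameter_names
  idx <- regmatches(pn, regexec("^a\\[(\\d+),(\\d+)\\]$", pn))
  keep <- lengths(idx) == 3
  if (!any(keep)) stop("no A-matrix parameters in this BMA", call. = FALSE)
  ii <- as.integer(vapply(idx[keep], `[`, "", 2))
  jj <- as.integer(vapply(idx[keep], `[`, "", 3))
  n <- max(ii, jj)
  est <- bma_conn$averaged_posterior$mean[paste0("mean:", pn[keep])]
  pp <- bma_conn$pp[paste0("mean:", pn[keep])]
  M <- matrix("", n, n)
  for (k in seq_along(ii)) {
    val <- if (ii[k] == jj[k]) self_connection_rate(est[k]) else est[k]
    M[ii[k], jj[k]] <-
      if (!is.na(pp[k]) && pp[k] > threshold || ii[k] == jj[k])
        format(round(val, digits)) else ""
  }
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  dimnames(M) <- list(to = roi_names, from = roi_names)
  if (!from_columns_to_rows) M <- t(M)
  M
}

#' Write a pipeline report to JSON plus matrix renderings
#'
#' Dumps the free energies, posterior model probabilities, winning models,
#' effect sizes and per-timespan means as JSON, and the thresholded
#' connectivity matrix as tab-delimited text with sub-threshold entries
#' blank.
#'
#' @param report A `tod_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tod_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per <- function(an) list(
    free_energies = an$bmc$free_energies,
    posterior_probs = an$bmc$posterior_probs,
    winning_id = an$bmc$winning_id,
    per_timespan_means = apply(an$bma$per_timespan_means, 1, as.list),
    pp = as.list(an$bma$pp))
  jsonlite::write_json(list(
    connectivity = per(report$connectivity),
    hemodynamic = per(report$hemodynamic),
    effect_sizes = as.list(report$effect_sizes),
    timing = as.list(report$timing)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  M <- render_connectivity_matrix(report$connectivity$bma)
  utils::write.table(M, file.path(dir, "connectivity_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}

#' Serialize / restore a cohort configuration
#'
#' @param config A [cohort_config()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_cohort_config()` returns the config.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, x)
}
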