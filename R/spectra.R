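#' Fit a multivariate autoregressive model by least squares
#'
#' @param series Numeric matrix, volumes x ROI, already demeaned.
#' @param order MAR order p (default 8, the convention for spectral DCM data
#'   features).
#' @return Object of class `mar_model`: list with `order`, `coeffs`
#'   (array p x n x n; `coeffs[k,,] %*% y[t-k]` contributes to the prediction
#'   of `y[t]`), `noise_cov` (n x n, symmetric PSD), `n_obs`.
#' @export
fit_mar <- function(series, order = 8) {
  series <- as.matrix(series)
  n <- ncol(series); Tn <- nrow(series)
  if (Tn <= order * n + 1)
    stop("too few volumes for the requested MAR order", call. = FALSE)
  if (order == 0)
    return(structure(list(order = 0L, coeffs = array(0, c(0, n, n)),
                          noise_cov = stats::cov(series), n_obs = Tn),
                     class = "mar_model"))
  Y <- series[(order + 1):Tn, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(k)
    series[(order + 1 - k):(Tn - k), , drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("ill-conditioned MAR regression; try a lower order", call. = FALSE)
  Bhat <- qr.coef(qrX, Y)                      # (order*n) x n
  resid <- Y - X %*% Bhat
  Sigma <- crossprod(resid) / (nrow(Y) - ncol(X))
  coeffs <- array(0, c(order, n, n))
  for (k in seq_len(order)) {
    blk <- Bhat[((k - 1) * n + 1):(k * n), , drop = FALSE]
    coeffs[k, , ] <- t(blk)                    # row i: prediction of ROI i
  }
  structure(list(order = as.integer(order), coeffs = coeffs,
                 noise_cov = (Sigma + t(Sigma)) / 2, n_obs = Tn),
            class = "mar_model")
}

#' Cross-spectral density implied by a MAR model
#'
#' `S(f) = TR * A(f)^-1 Sigma A(f)^-*` with
#' `A(f) = I - sum_k coeffs_k exp(-2*pi*i*f*k*TR)`; the TR factor converts
#' the per-sample spectral density to units of signal^2 per Hz.
#'
#' @param model A [fit_mar()] result.
#' @param freq Frequencies in Hz.
#' @param TR Sampling interval in seconds.
#' @return A [cross_spectrum()].
#' @export
mar_csd <- function(model, freq, TR) {
  stopifnot(inherits(model, "mar_model"))
  n <- ncol(model$noise_cov)
  S <- array(0i, c(n, n, length(freq)))
  for (j in seq_along(freq)) {
    Af <- diag(n) + 0i
    for (k in seq_len(model$order))
      Af <- Af - model$coeffs[k, , ] * exp(-2i * pi * freq[j] * k * TR)
    Ainv <- tryCatch(solve(Af), error = function(e)
      stop("MAR spectral matrix singular at f = ", freq[j], call. = FALSE))
    Sk <- TR * Ainv %*% model$noise_cov %*% Conj(t(Ainv))
    S[, , j] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectrum(freq, S)
}

#' Welch cross-spectral density estimate
#'
#' Averaged Hann-windowed segment periodograms, linearly interpolated to the
#' requested grid. Independent oracle for [mar_csd()]; not used in inversion.
#'
#' @param series Numeric matrix, volumes x ROI.
#' @param freq Frequencies in Hz; must lie within the resolvable band.
#' @param TR Sampling interval in seconds.
#' @param window_length Segment length (default: volumes/8 rounded down to a
#'   power of two, at least 32).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A [cross_spectrum()].
#' @export
welch_csd <- function(series, freq, TR,
                      window_length = max(32, 2^floor(log2(nrow(series) / 8))),
                      overlap = 0.5) {
  series <- as.matrix(series)
  Tn <- nrow(series); n <- ncol(series)
  if (window_length > Tn)
    stop("`window_length` exceeds the number of volumes", call. = FALSE)
  step <- max(1, floor(window_length * (1 - overlap)))
  starts <- seq(1, Tn - window_length + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_length) / (window_length + 1))
  U <- sum(w^2)
  fbin <- (seq_len(window_length) - 1) / (window_length * TR)
  if (min(freq) < fbin[2] || max(freq) > 1 / (2 * TR))
    stop("requested grid outside the resolvable band", call. = FALSE)
  acc <- array(0i, c(n, n, window_length))
  for (s0 in starts) {
    seg <- series[s0:(s0 + window_length - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    Fs <- stats::mvfft(seg)
    for (k in seq_len(window_length))
      acc[, , k] <- acc[, , k] + Fs[k, ] %o% Conj(Fs[k, ])
  }
  # one-segment-averaged two-sided density in signal^2 / Hz
  acc <- acc * (TR / (U * length(starts)))
  S <- array(0i, c(n, n, length(freq)))
  keep <- 2:(floor(window_length / 2))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    re <- stats::approx(fbin[keep], Re(acc[i, j, keep]), xout = freq, rule = 2)$y
    im <- stats::approx(fbin[keep], Im(acc[i, j, keep]), xout = freq, rule = 2)$y
    S[i, j, ] <- complex(real = re, imaginary = im)
  }
  for (k in seq_along(freq)) {
    Sk <- S[, , k, drop = FALSE]; dim(Sk) <- c(n, n)
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectrum(freq, S)
}

#' Map a cross-spectrum to the inversion feature vector
#'
#' Frequency-major ordering: for each frequency, the real parts of the upper
#' triangle including the diagonal (column-major, i <= j), then the imaginary
#' parts of the strict upper triangle (i < j). The map is invertible
#' ([unfeature_vector()]); length is `n_freq * n^2`.
#'
#' @param S A [cross_spectrum()].
#' @return Numeric vector.
#' @export
feature_vector <- function(S) {
  stopifnot(inherits(S, "cross_spectrum"))
  n <- dim(S$S)[1]
  ur <- which(upper.tri(diag(n), diag = TRUE))
  ui <- which(upper.tri(diag(n), diag = FALSE))
  unlist(lapply(seq_along(S$freq), function(k) {
    Sk <- S$S[, , k, drop = FALSE]; dim(Sk) <- c(n, n)
    c(Re(Sk[ur]), Im(Sk[ui]))
  }), use.names = FALSE)
}

#' @rdname feature_vector
#' @param x Feature vector produced by [feature_vector()].
#' @param freq The frequency grid it was computed on.
#' @param n_rois Number of regions.
#' @export
unfeature_vector <- function(x, freq, n_rois) {
  n <- n_rois
  per <- n^2
  stopifnot(length(x) == per * length(freq))
  ur <- which(upper.tri(diag(n), diag = TRUE))
  ui <- which(upper.tri(diag(n), diag = FALSE))
  S <- array(0i, c(n, n, length(freq)))
  for (k in seq_along(freq)) {
    blk <- x[((k - 1) * per + 1):(k * per)]
    Sk <- matrix(0i, n, n)
    Sk[ur] <- blk[seq_along(ur)]
    Sk[ui] <- Sk[ui] + 1i * blk[length(ur) + seq_along(ui)]
    Sk <- Sk + Conj(t(Sk)) - diag(Re(diag(Sk)))
    S[, , k] <- Sk
  }
  cross_spectrum(freq, S)
}

#' Demean (and optionally rescale) ROI series before spectral estimation
#'
#' Columns are demeaned; the whole matrix is divided by a single global
#' normalization constant (the pooled standard deviation) when
#' `normalize = TRUE`, recorded in the `"norm_constant"` attribute so
#' amplitudes remain interpretable.
#'
#' @param series Volumes x ROI matrix.
#' @param normalize Logical; default FALSE.
#' @return Demeaned matrix with attribute `norm_constant`.
#' @export
standardize_series <- function(series, normalize = FALSE) {
  series <- as.matrix(series)
  out <- sweep(series, 2, colMeans(series))
  cst <- 1
  if (normalize) {
    cst <- sqrt(mean(out^2))
    if (cst == 0) stop("constant series cannot be normalized", call. = FALSE)
    out <- out / cst
  }
  attr(out, "norm_constant") <- cst
  out
}
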