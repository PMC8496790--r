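#' Gaussian spatial binning
#'
#' Convolves every frame with a normalized 2-D Gaussian kernel of size
#' 3 x 3 or 5 x 5 (sigma = kernel_size / 4, truncated and renormalized so
#' the kernel sums to 1), the standard noise-reduction step for
#' optical-mapping movies. Borders are handled by edge replication, so a
#' spatially constant frame passes through unchanged.
#'
#' @param movie a [voltage_movie()].
#' @param kernel_size 3 or 5.
#' @return the binned [voltage_movie()].
#' @export
spatial_bin <- function(movie, kernel_size = 3L) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (!kernel_size %in% c(3L, 5L))
    stop("kernel_size must be 3 or 5", call. = FALSE)
  k <- gaussian_kernel(kernel_size)
  half <- (kernel_size - 1L) %/% 2L
  d <- dim(movie$data)
  out <- array(0, dim = d)
  for (f in seq_len(d[3])) {
    padded <- pad_replicate(movie$data[, , f], half)
    acc <- matrix(0, d[1], d[2])
    for (di in -half:half) {
      for (dj in -half:half) {
        acc <- acc + k[di + half + 1L, dj + half + 1L] *
          padded[(1L + half + di):(d[1] + half + di),
                 (1L + half + dj):(d[2] + half + dj)]
      }
    }
    out[, , f] <- acc
  }
  voltage_movie(out, movie$frame_rate_hz, movie$pixel_size_mm)
}

gaussian_kernel <- function(size) {
  half <- (size - 1L) %/% 2L
  sigma <- size / 4
  ax <- (-half):half
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k / sum(k)
}

pad_replicate <- function(mat, n) {
  if (n == 0L) return(mat)
  ri <- c(rep(1L, n), seq_len(nrow(mat)), rep(nrow(mat), n))
  ci <- c(rep(1L, n), seq_len(ncol(mat)), rep(ncol(mat), n))
  mat[ri, ci]
}

#' Temporal bandpass filter
#'
#' Filters each pixel's trace with a zero-phase Butterworth filter (applied
#' forward and backward, so upstrokes are not shifted in time). With the low
#' edge at 0 Hz — the configuration used for optical-mapping movies, which
#' must keep the DC level — the filter is a low-pass at `high_hz`; a
#' positive low edge gives a bandpass.
#'
#' @param movie a [voltage_movie()].
#' @param low_hz lower band edge (0 = low-pass).
#' @param high_hz upper band edge; must be below the Nyquist frequency.
#' @param order Butterworth order (default 4).
#' @return the filtered [voltage_movie()].
#' @export
temporal_filter <- function(movie, low_hz = 0, high_hz = 100, order = 4L) {
  stopifnot(inherits(movie, "voltage_movie"))
  nyq <- movie$frame_rate_hz / 2
  if (high_hz >= nyq)
    stop("high_hz must be below the Nyquist frequency ", nyq, " Hz", call. = FALSE)
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  filt <- if (low_hz == 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  d <- dim(movie$data)
  nt <- d[3]
  # constant (hold) padding plus mean anchoring keeps the forward-backward
  # pass free of start/end transients and makes DC traces exact; unlike
  # reflection padding it cannot mirror an early upstroke into a spurious
  # pre-recording deflection
  padlen <- min(nt - 1L, ceiling(3 * movie$frame_rate_hz / high_hz))
  flat <- matrix(movie$data, nrow = d[1] * d[2], ncol = nt)
  out <- t(apply(flat, 1L, function(tr) {
    mu <- mean(tr)
    x <- tr - mu
    xp <- c(rep(x[1], padlen), x, rep(x[nt], padlen))
    y <- signal::filtfilt(filt, xp)
    y[(padlen + 1L):(padlen + nt)] + mu
  }))
  voltage_movie(array(out, dim = d), movie$frame_rate_hz, movie$pixel_size_mm)
}

#' Drift correction and amplitude normalization
#'
#' Per pixel, estimates a slow polynomial baseline (default order 2) that
#' tracks the diastolic level underneath the action potentials: after an
#' initial least-squares fit, the fit is repeated on the diastolic samples
#' only — those in the lower band of the residual range — so the baseline
#' settles under the upward AP deflections instead of through them. The
#' baseline is subtracted and the residual affinely rescaled so its
#' minimum maps to 0 and its maximum to 1. Pixels with a (numerically)
#' constant trace map to all-zeros rather than dividing by a vanishing
#' range. The operation is idempotent: applying it twice equals applying
#' it once (up to small numerical differences from re-selecting the
#' diastolic band).
#'
#' @param movie a [voltage_movie()].
#' @param poly_order baseline polynomial order (default 2).
#' @param baseline_iter refinement iterations of the diastole selection
#'   (default 4).
#' @param baseline_band fraction of the residual range counted as
#'   diastolic (default 0.3).
#' @return the normalized [voltage_movie()]; values in \[0, 1\].
#' @export
drift_correct_normalize <- function(movie, poly_order = 2L,
                                    baseline_iter = 4L,
                                    baseline_band = 0.3) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$data)
  nt <- d[3]
  tt <- seq_len(nt) / nt
  basis <- stats::poly(tt, degree = poly_order, raw = FALSE)
  X <- cbind(1, basis)
  qrX <- qr(X)
  ncoef <- ncol(X)
  # precomputed products for the per-pixel weighted normal equations
  XX <- matrix(0, nt, ncoef * ncoef)
  for (i in seq_len(ncoef)) for (j in seq_len(ncoef))
    XX[, (i - 1L) * ncoef + j] <- X[, i] * X[, j]

  # all pixels at once: traces as columns; the iteration starts from a
  # constant low-quantile level — starting from the full least-squares fit
  # can select only one end of the trace and extrapolate wildly
  Y <- t(matrix(movie$data, nrow = d[1] * d[2], ncol = nt))
  npix <- ncol(Y)
  B <- matrix(apply(Y, 2L, stats::quantile, probs = 0.1),
              nt, npix, byrow = TRUE)
  for (it in seq_len(baseline_iter)) {
    R <- Y - B
    lo <- apply(R, 2L, min)
    band <- baseline_band * (apply(R, 2L, max) - lo)
    W <- (R <= rep(lo + band, each = nt)) * 1
    A <- crossprod(W, XX)          # npix x ncoef^2
    rhs <- crossprod(W * Y, X)     # npix x ncoef
    coefs <- matrix(0, ncoef, npix)
    for (p in seq_len(npix)) {
      Ap <- matrix(A[p, ], ncoef, ncoef)
      cf <- tryCatch(solve(Ap, rhs[p, ]), error = function(e) NULL)
      if (is.null(cf)) cf <- qr.coef(qrX, Y[, p])   # fall back to plain LS
      coefs[, p] <- cf
    }
    B <- X %*% coefs
  }
  resid <- Y - B
  lo <- apply(resid, 2L, min)
  hi <- apply(resid, 2L, max)
  rng <- hi - lo
  flat <- rng <= max(rng, 1) * 1e-12
  rng[flat] <- 1
  norm <- sweep(sweep(resid, 2L, lo, "-"), 2L, rng, "/")
  norm[, flat] <- 0
  voltage_movie(array(t(norm), dim = d), movie$frame_rate_hz, movie$pixel_size_mm)
}

#' Signal-to-noise mask
#'
#' Flags pixels whose trace carries a detectable activation signal. Per
#' pixel, a slow polynomial baseline (drift) is removed, the noise SD is
#' estimated robustly from frame-to-frame differences (median absolute
#' successive difference, Gaussian-scaled), and the SNR is the detrended
#' peak-to-peak amplitude divided by the expected peak-to-peak excursion of
#' pure noise of that SD over the movie length. A noise-only pixel
#' therefore scores about 1 regardless of the noise level, while an
#' activation trace scores its amplitude in units of the noise band.
#' Pixels with SNR at or above `snr_threshold` are retained; noise-free
#' active pixels get a large finite SNR.
#'
#' The successive-difference noise estimate assumes the noise is not yet
#' strongly temporally correlated: apply this mask before (or instead of
#' after) narrow low-pass filtering. [preprocess_movie()] computes it on
#' the spatially binned, unfiltered movie.
#'
#' @param movie a [voltage_movie()].
#' @param snr_threshold retention threshold (> 0; default 3).
#' @param detrend_order polynomial order of the baseline removed before
#'   measuring the amplitude (default 2, as in the drift correction).
#' @return logical matrix, `TRUE` = analyzed. Errors if no pixel survives.
#' @export
snr_mask <- function(movie, snr_threshold = 3, detrend_order = 2L) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (snr_threshold <= 0) stop("snr_threshold must be positive", call. = FALSE)
  d <- dim(movie$data)
  nt <- d[3]
  X <- cbind(1, stats::poly(seq_len(nt) / nt, degree = detrend_order))
  Y <- t(matrix(movie$data, nrow = d[1] * d[2], ncol = nt))
  resid <- Y - X %*% qr.coef(qr(X), Y)
  amp <- apply(resid, 2L, function(r) max(r) - min(r))
  noise_sd <- apply(resid, 2L, function(r) {
    stats::median(abs(diff(r))) / sqrt(2) * 1.4826
  })
  expected_noise_range <- 2 * stats::qnorm(1 - 0.5 / nt) * noise_sd
  snr <- ifelse(expected_noise_range > 1e-9 * pmax(amp, 1),
                amp / expected_noise_range, 1e6)
  snr[amp <= 0] <- 0
  mask <- matrix(snr >= snr_threshold, d[1], d[2])
  if (!any(mask)) stop("empty mask: no pixel reaches the SNR threshold", call. = FALSE)
  mask
}

#' Full preprocessing chain
#'
#' Gaussian binning, temporal low-pass, drift correction + normalization,
#' then SNR masking, in that order.
#'
#' @param movie a raw [voltage_movie()].
#' @param kernel_size binning kernel size (3 or 5).
#' @param low_hz,high_hz band edges for [temporal_filter()].
#' @param filter_order Butterworth order.
#' @param drift_order baseline polynomial order.
#' @param snr_threshold see [snr_mask()].
#' @return list with `movie` (the processed [voltage_movie()]) and `mask`
#'   (the [snr_mask()] result).
#' @export
preprocess_movie <- function(movie, kernel_size = 3L, low_hz = 0,
                             high_hz = 100, filter_order = 4L,
                             drift_order = 2L, snr_threshold = 3) {
  binned <- spatial_bin(movie, kernel_size)
  # the mask's noise estimator needs uncorrelated noise: compute it before
  # the narrow low-pass
  mask <- snr_mask(binned, snr_threshold, detrend_order = drift_order)
  out <- temporal_filter(binned, low_hz, high_hz, order = filter_order)
  out <- drift_correct_normalize(out, poly_order = drift_order)
  list(movie = out, mask = mask)
}
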