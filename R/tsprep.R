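# Temporal preprocessing of region (or voxel) BOLD series:
# nuisance regression -> zero-phase band-pass -> (voxel mode) smoothing.
# The order is fixed in prep_pipeline(); permuting regression and filtering
# leaves filtered confound energy in the residuals.

#' Preprocessing configuration
#'
#' @param f_low,f_high band-pass corner frequencies in Hz (defaults 0.009
#'   and 0.08, the conventional resting-state band).
#' @param fwhm smoothing kernel full width at half maximum in mm (voxel
#'   mode only; default 3).
#' @param order Butterworth order per pass direction.
#' @return list of class `prep_config`.
#' @export
prep_config <- function(f_low = 0.009, f_high = 0.08, fwhm = 3, order = 2L) {
  if (f_low <= 0 || f_high <= f_low) stop("need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high, fwhm = fwhm,
                 order = as.integer(order)),
            class = "prep_config")
}

#' Regress nuisance signals out of a BOLD series
#'
#' Ordinary least squares of each region's series on an intercept plus the
#' confound regressors; residuals are returned with the region mean added
#' back, so the series stays on its original scale (correlations are
#' mean-invariant).
#'
#' @param series a `bold_series` (or plain R x T matrix).
#' @param regressors T x K confound matrix; defaults to the regressors
#'   stored on the series by the simulator.
#' @return the series with confound contributions removed.
#' @export
regress_nuisance <- function(series, regressors = NULL) {
  v <- .series_values(series)
  if (is.null(regressors) && inherits(series, "bold_series"))
    regressors <- series$nuisance
  if (is.null(regressors) || NCOL(regressors) == 0L)
    return(series)
  regressors <- as.matrix(regressors)
  Tn <- ncol(v)
  if (nrow(regressors) != Tn)
    stop("regressor matrix must have T rows")
  X <- cbind(`(intercept)` = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (is.null(dropped)) dropped <- "unnamed"
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(v)                          # T x R
  res <- qr.resid(qrX, Y)            # residuals per region
  mu <- colMeans(Y)
  out_values <- t(res + rep(mu, each = Tn))
  .series_replace(series, out_values)
}

#' Band-pass filter a BOLD series
#'
#' Zero-phase forward-backward Butterworth filter (order 2 per pass).  The
#' effective amplitude response is the squared single-pass response, so
#' pass-band sinusoids are attenuated by less than 10 percent while
#' frequencies at twice the upper corner are attenuated by more than 90
#' percent at TR = 3 s.
#'
#' @param series a `bold_series` (or R x T matrix with attribute-free TR
#'   given via `TR`).
#' @param config a [prep_config()].
#' @param TR repetition time, required only for plain matrices.
#' @return the filtered series.
#' @export
bandpass <- function(series, config = prep_config(), TR = NULL) {
  v <- .series_values(series)
  if (inherits(series, "bold_series")) TR <- series$TR
  if (is.null(TR)) stop("TR required")
  nyq <- 1 / (2 * TR)
  if (config$f_high >= nyq)
    stop(sprintf("f_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 config$f_high, nyq))
  if (ncol(v) < 8L) stop("series too short to filter (T >= 8 required)")
  bf <- signal::butter(config$order, c(config$f_low, config$f_high) / nyq,
                       type = "pass")
  mu <- rowMeans(v)
  centered <- v - mu
  filt <- t(apply(centered, 1L, function(x) signal::filtfilt(bf, x)))
  .series_replace(series, filt + mu)
}

#' Gaussian spatial smoothing of a voxel volume series (voxel mode)
#'
#' Separable 3-D Gaussian with sigma = FWHM / 2.3548 voxels (FWHM given in
#' mm, divided by the voxel size).  Boundaries are handled by reflective
#' padding, which conserves the per-volume total intensity.
#'
#' @param vol a 3-D array (x, y, z) or 4-D array (x, y, z, t).
#' @param fwhm full width at half maximum in mm.
#' @param voxel_size voxel edge length in mm.
#' @return smoothed array of the same shape.
#' @export
spatial_smooth <- function(vol, fwhm, voxel_size = 1) {
  if (fwhm < 0) stop("FWHM must be non-negative")
  if (fwhm == 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  dims <- dim(vol)
  if (length(dims) == 3L) return(.smooth3d(vol, kern))
  if (length(dims) == 4L) {
    for (t in seq_len(dims[4L])) vol[, , , t] <- .smooth3d(vol[, , , t], kern)
    return(vol)
  }
  stop("vol must be a 3-D or 4-D array")
}

.smooth3d <- function(a, kern) {
  for (axis in 1:3) a <- .convolve_axis(a, kern, axis)
  a
}

# reflect-padded 1-D convolution along one axis of a 3-D array
.convolve_axis <- function(a, kern, axis) {
  half <- (length(kern) - 1L) %/% 2L
  n <- dim(a)[axis]
  pad_idx <- c(rev(seq_len(min(half, n))), seq_len(n),
               rev(n + 1L - seq_len(min(half, n))))
  # short axes: clamp reflection
  while (length(pad_idx) < n + 2L * half)
    pad_idx <- c(pad_idx[1L], pad_idx, pad_idx[length(pad_idx)])
  apply_axis <- function(x) {
    xp <- x[pad_idx]
    out <- numeric(n)
    for (i in seq_len(n))
      out[i] <- sum(xp[i:(i + 2L * half)] * rev(kern))
    out
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1L])
  m <- apply(m, 2L, apply_axis)
  ap <- array(m, d)
  aperm(ap, order(perm))
}

#' Run the fixed preprocessing pipeline on one series
#'
#' Nuisance regression first, then band-pass filtering.  The order is
#' enforced: filtering first would leave the in-band projection of the
#' confounds in the data.
#'
#' @param series a `bold_series`.
#' @param config a [prep_config()].
#' @param regressors optional T x K confounds (default: stored regressors).
#' @return preprocessed `bold_series`.
#' @export
prep_pipeline <- function(series, config = prep_config(), regressors = NULL) {
  series <- regress_nuisance(series, regressors)
  bandpass(series, config)
}

.series_values <- function(series) {
  if (inherits(series, "bold_series")) series$values else as.matrix(series)
}

.series_replace <- function(series, values) {
  if (inherits(series, "bold_series")) {
    series$values <- values
    series
  } else values
}
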