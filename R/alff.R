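#' Bundle a 4D BOLD series with its affine and repetition time
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param affine 4x4 affine matrix.
#' @param tr_s Repetition time in seconds.
#' @return A list of class `vol_series`.
#' @export
vol_series <- function(data, affine, tr_s) {
  stopifnot(length(dim(data)) == 4, tr_s > 0)
  structure(list(data = data, affine = affine, tr_s = tr_s,
                 detrended = FALSE, excluded = FALSE),
            class = "vol_series")
}

#' Discard initial volumes, screen head motion and detrend
#'
#' Removes the first `n_discard` volumes (T1-equilibration period), flags
#' the subject as excluded when the supplied motion summary exceeds 3 mm
#' maximum displacement or 3 degrees of rotation, and removes the per-voxel
#' linear trend.
#'
#' @param series A [vol_series()].
#' @param n_discard Number of initial volumes to drop.
#' @param motion_summary Optional list or named vector with
#'   `max_displacement_mm` and `max_rotation_deg`.
#' @param displacement_limit_mm,rotation_limit_deg Exclusion limits
#'   (defaults 3 mm and 3 degrees).
#' @return The preprocessed `vol_series`; `$excluded` is `TRUE` when the
#'   motion limits are exceeded.
#' @export
preprocess_series <- function(series, n_discard = 8, motion_summary = NULL,
                              displacement_limit_mm = 3,
                              rotation_limit_deg = 3) {
  stopifnot(inherits(series, "vol_series"))
  nt <- dim(series$data)[4]
  if (nt < n_discard + 2) abort("series too short for the requested discard")
  kept <- series$data[, , , (n_discard + 1):nt, drop = FALSE]
  dims <- dim(kept)
  tn <- dims[4]
  flat <- matrix(kept, prod(dims[1:3]), tn)     # voxels x time
  tt <- seq_len(tn)
  x <- cbind(1, tt - mean(tt))
  proj <- x %*% solve(crossprod(x), t(x))
  flat <- flat - flat %*% t(proj)               # per-voxel linear detrend
  series$data <- array(flat, dims)
  series$detrended <- TRUE
  if (!is.null(motion_summary)) {
    ms <- as.list(motion_summary)
    series$excluded <- isTRUE(ms$max_displacement_mm > displacement_limit_mm) ||
      isTRUE(ms$max_rotation_deg > rotation_limit_deg)
  }
  series
}

# frequency vector of an N-point DFT at sampling interval tr_s (positive
# half-spectrum, bins 0 .. floor(N/2))
dft_freqs <- function(n, tr_s) {
  (0:(n %/% 2)) / (n * tr_s)
}

#' Band-pass a time series by Fourier-coefficient masking
#'
#' Zeroes every DFT bin whose frequency lies outside `[band[1], band[2]]`
#' (band edges inclusive) and inverts the transform; no taper, transform
#' length equal to the series length.
#'
#' @param x Numeric time series.
#' @param tr_s Sampling interval in seconds.
#' @param band Length-2 frequency band in Hz.
#' @return The band-passed real series.
#' @export
bandpass_series <- function(x, tr_s, band = c(0.01, 0.08)) {
  n <- length(x)
  nyquist <- 1 / (2 * tr_s)
  if (band[2] > nyquist + 1e-12) abort("band upper edge exceeds the Nyquist frequency")
  k <- 0:(n - 1)
  freqs_all <- pmin(k, n - k) / (n * tr_s)
  keep <- freqs_all >= band[1] - 1e-12 & freqs_all <= band[2] + 1e-12
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Band-limited spectral amplitude of one time series
#'
#' Discrete Fourier transform of the full series (no taper), single-sided
#' amplitude `2|X_k|/N` per positive-frequency bin, averaged over the bins
#' with `band[1] <= f <= band[2]`. Equal, by construction, to first
#' band-passing the series by Fourier masking and then averaging the
#' in-band amplitudes.
#'
#' @param x Numeric time series (at least 2 samples).
#' @param tr_s Sampling interval in seconds.
#' @param band Length-2 frequency band in Hz; must not exceed Nyquist.
#' @return Scalar amplitude (arbitrary units, non-negative).
#' @export
bandlimited_amplitude <- function(x, tr_s, band = c(0.01, 0.08)) {
  n <- length(x)
  if (n < 2) abort("need at least 2 samples")
  nyquist <- 1 / (2 * tr_s)
  if (band[2] > nyquist + 1e-12) abort("band upper edge exceeds the Nyquist frequency")
  freqs <- dft_freqs(n, tr_s)
  bins <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
  if (length(bins) == 0) return(0)
  amp <- 2 * Mod(fft(x)[bins]) / n
  mean(amp)
}

#' Voxelwise ALFF map
#'
#' Applies [bandlimited_amplitude()] at every in-mask voxel of a
#' (preprocessed) series; voxels outside the brain mask are set to 0.
#'
#' @param series A detrended [vol_series()] (see [preprocess_series()]).
#' @param mask Logical 3D brain mask matching the series grid.
#' @param band Frequency band in Hz (default 0.01-0.08).
#' @return A list of class `alff_map` with `data` (3D array), `affine`,
#'   `band` and `mask`.
#' @export
compute_alff_map <- function(series, mask, band = c(0.01, 0.08)) {
  stopifnot(inherits(series, "vol_series"))
  dims <- dim(series$data)
  if (!identical(dim(mask), dims[1:3])) abort("mask and series shapes disagree")
  vin <- which(mask)
  if (length(vin) == 0) abort("mask is empty")
  nt <- dims[4]
  nyquist <- 1 / (2 * series$tr_s)
  if (band[2] > nyquist + 1e-12) abort("band upper edge exceeds the Nyquist frequency")
  flat <- matrix(series$data, prod(dims[1:3]), nt)[vin, , drop = FALSE]
  freqs <- dft_freqs(nt, series$tr_s)
  bins <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
  spec <- mvfft(t(flat))                        # time x voxels
  amp <- 2 * Mod(spec[bins, , drop = FALSE]) / nt
  out <- array(0, dims[1:3])
  out[vin] <- colMeans(amp)
  structure(list(data = out, affine = series$affine, band = band, mask = mask),
            class = "alff_map")
}

#' Gaussian smoothing of a 3D volume
#'
#' Circular (FFT-based) convolution with an isotropic Gaussian kernel of
#' the requested FWHM; `fwhm_mm = 0` returns the input unchanged. The
#' kernel is normalised to unit sum, so the total image sum is conserved.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Kernel full width at half maximum in millimetres.
#' @param voxel_size_mm Voxel edge length in millimetres.
#' @return The smoothed array.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) abort("fwhm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  dims <- dim(vol)
  sigma <- fwhm_mm / (sqrt(8 * log(2)) * voxel_size_mm)
  kern1 <- lapply(dims, function(d) {
    pos <- c(0:(d %/% 2), -((d - d %/% 2 - 1):1))   # circular coordinates
    k <- exp(-pos^2 / (2 * sigma^2))
    k / sum(k)
  })
  kernel <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  Re(fft(fft(vol) * fft(kernel), inverse = TRUE)) / prod(dims)
}

#' Smooth a 3D map (identity at zero width)
#'
#' Front end to [gaussian_smooth_3d()] used for ALFF maps and grey-matter
#' maps.
#'
#' @inheritParams gaussian_smooth_3d
#' @return The smoothed array.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 3) {
  gaussian_smooth_3d(vol, fwhm_mm, voxel_size_mm)
}

#' Estimate the smoothness (FWHM) of a 3D field
#'
#' Gaussian-autocorrelation estimator: for white noise smoothed with a
#' Gaussian of width sigma, the lag-1 voxel correlation along an axis is
#' `exp(-d^2 / (4 sigma^2))`. The per-axis estimates are averaged.
#' Provided for reporting; cluster simulation uses the configured FWHM.
#'
#' @param vol 3D numeric array.
#' @param mask Logical 3D mask.
#' @param voxel_size_mm Voxel edge length in millimetres.
#' @return Estimated FWHM in millimetres.
#' @export
estimate_fwhm <- function(vol, mask, voxel_size_mm = 3) {
  dims <- dim(vol)
  est <- vapply(1:3, function(a) {
    idx1 <- slice.index(array(0, dims), a) < dims[a]
    shift <- function(x) {
      perm <- c(a, setdiff(1:3, a))
      xs <- aperm(x, perm)
      xs <- xs[c(2:dims[a], 1), , , drop = FALSE]
      aperm(xs, order(perm))
    }
    ok <- idx1 & mask & shift(mask)
    r <- cor(vol[ok], shift(vol)[ok])
    if (is.na(r) || r <= 0) return(NA_real_)
    sigma <- sqrt(-1 / (4 * log(r)))
    sigma * sqrt(8 * log(2)) * voxel_size_mm
  }, numeric(1))
  mean(est, na.rm = TRUE)
}
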