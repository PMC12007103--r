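#' Hologram brightness, contrast and SNR
#'
#' Brightness `M` is the mean intensity, contrast `delta_M` its standard
#' deviation (both in the hologram's units, a.u. or camera gray levels).
#' When a noise-free reference of the same scene is supplied, the
#' signal-to-noise ratio is the reference contrast over the residual noise
#' standard deviation: `snr = sd(reference) / sd(I - reference)`.
#'
#' @param h A [hologram()].
#' @param reference Optional noise-free [hologram()] of the same scene.
#' @return A one-row tibble with columns `M`, `delta_M` and `snr`
#'   (`NA` without a reference).
#' @export
hologram_stats <- function(h, reference = NULL) {
  stopifnot(inherits(h, "hologram"))
  i <- h$intensity
  snr <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "hologram"))
    if (!all(dim(reference$intensity) == dim(i)))
      stop("hologram_stats: reference shape mismatch", call. = FALSE)
    noise_sd <- stats::sd(i - reference$intensity)
    snr <- stats::sd(reference$intensity) / noise_sd
  }
  tibble::tibble(M = mean(i), delta_M = stats::sd(i), snr = snr)
}

#' Root-mean-square reconstruction error
#'
#' `sqrt(mean((recon - truth)^2))` over an optional logical mask. For phase
#' maps the global piston (masked mean difference) is removed first, since
#' in-line holography cannot fix the global phase offset.
#'
#' @param recon,truth Numeric matrices of the same shape.
#' @param mask Optional logical matrix selecting the pixels to compare.
#' @param piston If `TRUE` (phase inputs), subtract the masked mean
#'   difference before computing the error.
#' @return A single nonnegative number.
#' @export
rms_error <- function(recon, truth, mask = NULL, piston = FALSE) {
  stopifnot(is.matrix(recon), is.matrix(truth))
  if (!all(dim(recon) == dim(truth)))
    stop("rms_error: shape mismatch", call. = FALSE)
  d <- recon - truth
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(recon)))
      stop("rms_error: mask shape mismatch", call. = FALSE)
    d <- d[mask]
    if (length(d) == 0L) stop("rms_error: empty mask", call. = FALSE)
  }
  if (piston) d <- d - mean(d)
  sqrt(mean(d^2))
}

# Banded matrix performing a 'valid' 1-D correlation with weights w.
valid_band <- function(n, w) {
  L <- length(w)
  if (n < L) stop("ssim_index: image smaller than the 11 px window", call. = FALSE)
  m <- matrix(0, n - L + 1L, n)
  for (i in seq_len(n - L + 1L)) m[i, i:(i + L - 1L)] <- w
  m
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian window of standard deviation 1.5,
#' `K1 = 0.01`, `K2 = 0.03`, averaged over all complete windows. The dynamic
#' range defaults to `max(truth) - min(truth)`.
#'
#' @param recon,truth Numeric matrices of the same shape (>= 11 px each way).
#' @param dynamic_range Optional positive value of the data range `L`.
#' @return SSIM in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim_index <- function(recon, truth, dynamic_range = NULL) {
  stopifnot(is.matrix(recon), is.matrix(truth))
  if (!all(dim(recon) == dim(truth)))
    stop("ssim_index: shape mismatch", call. = FALSE)
  if (is.null(dynamic_range)) dynamic_range <- max(truth) - min(truth)
  if (!is.finite(dynamic_range) || dynamic_range <= 0)
    stop("ssim_index: dynamic range must be > 0", call. = FALSE)
  w <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- w / sum(w)
  Kr <- valid_band(nrow(recon), w)
  Kc <- valid_band(ncol(recon), w)
  smooth <- function(x) Kr %*% x %*% t(Kc)
  mu1 <- smooth(recon); mu2 <- smooth(truth)
  s11 <- smooth(recon^2) - mu1^2
  s22 <- smooth(truth^2) - mu2^2
  s12 <- smooth(recon * truth) - mu1 * mu2
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map)
}

#' Background (object-free area) standard deviation
#'
#' The `S` quality measure: standard deviation of the reconstructed phase
#' over an object-free rectangle, in radians.
#'
#' @param phase Numeric matrix (radians).
#' @param roi Rectangle `c(row_start, row_end, col_start, col_end)` in
#'   0-based, half-open pixel coordinates (`row_start <= r < row_end`).
#' @return Standard deviation of `phase` inside the rectangle.
#' @export
background_std <- function(phase, roi) {
  stopifnot(is.matrix(phase), length(roi) == 4L)
  r0 <- roi[1]; r1 <- roi[2]; c0 <- roi[3]; c1 <- roi[4]
  if (r0 < 0 || c0 < 0 || r1 > nrow(phase) || c1 > ncol(phase) ||
      r1 <= r0 || c1 <= c0)
    stop("background_std: roi must be a nonempty rectangle inside the image",
         call. = FALSE)
  stats::sd(phase[(r0 + 1):r1, (c0 + 1):c1])
}

#' Convert phase to physical thickness and back
#'
#' For a sample of refractive index `n_sample` in a medium of index
#' `n_medium`, a measured phase delay maps to thickness as
#' `t = phase * wavelength / (2 pi (n_sample - n_medium))`; the inverse is
#' exact.
#'
#' @param phase Phase in radians.
#' @param thickness Thickness in meters.
#' @param wavelength Wavelength in meters.
#' @param n_sample,n_medium Refractive indices (must differ).
#' @return Thickness in meters (`thickness_from_phase`) or phase in radians
#'   (`phase_from_thickness`); vectorized.
#' @examples
#' thickness_from_phase(8.47e-2, 561e-9, 1.47, 1.0)  # ~16 nm
#' @export
thickness_from_phase <- function(phase, wavelength, n_sample, n_medium = 1.0) {
  if (n_sample == n_medium)
    stop("thickness_from_phase: refractive indices must differ", call. = FALSE)
  phase * wavelength / (2 * pi * (n_sample - n_medium))
}

#' @rdname thickness_from_phase
#' @export
phase_from_thickness <- function(thickness, wavelength, n_sample, n_medium = 1.0) {
  if (n_sample == n_medium)
    stop("phase_from_thickness: refractive indices must differ", call. = FALSE)
  2 * pi * (n_sample - n_medium) * thickness / wavelength
}

#' Evaluate a reconstruction against ground truth
#'
#' Computes the piston-removed RMS error and SSIM of a reconstructed phase
#' map against the truth, plus the background standard deviation `S` when an
#' object-free rectangle is given.
#'
#' @param recon_phase,truth_phase Numeric phase matrices (radians).
#' @param roi Optional object-free rectangle for [background_std()]
#'   (0-based, half-open).
#' @param dynamic_range Optional SSIM dynamic range; defaults to the range
#'   of `truth_phase`.
#' @return A one-row tibble with columns `rms`, `ssim` and `S`.
#' @export
evaluate_reconstruction <- function(recon_phase, truth_phase, roi = NULL,
                                    dynamic_range = NULL) {
  aligned <- recon_phase - (mean(recon_phase) - mean(truth_phase))
  tibble::tibble(
    rms = rms_error(recon_phase, truth_phase, piston = TRUE),
    ssim = ssim_index(aligned, truth_phase, dynamic_range),
    S = if (is.null(roi)) NA_real_ else background_std(recon_phase, roi)
  )
}
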