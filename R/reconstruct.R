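#' Reconstruction settings
#'
#' Bundles the reconstructor selection and its tuning parameters.
#'
#' @param method `"iga"`, `"gs"`, `"ga"` or `"ghr"`.
#' @param iterations Number of full Gerchberg-Saxton cycles `T` (>= 1).
#'   100 gives well-converged results on simulated data; 10 is enough for
#'   timing comparisons.
#' @param sigma Gaussian kernel standard deviation in pixels splitting the
#'   low-pass (GS) and high-pass (GA) bands of IGA; ignored by the other
#'   methods. 2 is a robust default (values around 1-4 behave similarly).
#' @param hologram_to_amplitude How a recorded intensity becomes an
#'   amplitude: `"sqrt"` (physical: cameras record intensity) or
#'   `"identity"` (treat the normalized intensity itself as the amplitude).
#' @param pad_factor Propagation padding inside reconstruction loops; 1
#'   (periodic, default) or 2 (zero-padded).
#' @param strict_band If `TRUE`, IGA additionally low-passes the GS-path
#'   output before summation so the two paths occupy exactly complementary
#'   bands; the default `FALSE` follows the plain two-path scheme.
#' @return An object of class `reconstruction_settings`.
#' @export
reconstruction_settings <- function(method = c("iga", "gs", "ga", "ghr"),
                                    iterations = 100L, sigma = 2,
                                    hologram_to_amplitude = c("sqrt", "identity"),
                                    pad_factor = 1L, strict_band = FALSE) {
  method <- match.arg(method)
  hologram_to_amplitude <- match.arg(hologram_to_amplitude)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("reconstruction_settings: iterations must be >= 1", call. = FALSE)
  if (method == "iga" && (!is.finite(sigma) || sigma <= 0))
    stop("reconstruction_settings: sigma must be > 0 for iga", call. = FALSE)
  if (!as.integer(pad_factor) %in% c(1L, 2L))
    stop("reconstruction_settings: pad_factor must be 1 or 2", call. = FALSE)
  structure(list(method = method, iterations = iterations, sigma = sigma,
                 hologram_to_amplitude = hologram_to_amplitude,
                 pad_factor = as.integer(pad_factor),
                 strict_band = isTRUE(strict_band)),
            class = "reconstruction_settings")
}

#' Normalize a hologram and extract its amplitude
#'
#' Divides the intensity by its mean (so camera units drop out) and converts
#' to amplitude: `sqrt` mode returns `sqrt(I / mean(I))` (mean squared
#' amplitude 1), `identity` mode returns `I / mean(I)` (mean amplitude 1).
#'
#' @param h A [hologram()].
#' @param mode `"sqrt"` or `"identity"`.
#' @return Nonnegative numeric matrix of amplitudes.
#' @export
normalize_hologram <- function(h, mode = c("sqrt", "identity")) {
  stopifnot(inherits(h, "hologram"))
  mode <- match.arg(mode)
  m <- mean(h$intensity)
  if (m <= 0) stop("normalize_hologram: hologram has zero mean", call. = FALSE)
  a <- h$intensity / m
  if (mode == "sqrt") sqrt(a) else a
}

frame_amplitudes <- function(stack, mode) {
  lapply(stack$frames, normalize_hologram, mode = mode)
}

#' Single-frame Gabor holography reconstruction (GHR)
#'
#' Lifts the normalized hologram amplitude to a zero-phase field at the
#' camera plane and backpropagates it to the object plane. The twin image is
#' present by construction (the camera records no phase).
#'
#' @param h A [hologram()] (or a single-frame [hologram_stack()]).
#' @param settings A [reconstruction_settings()].
#' @return A [complex_field()] at the object plane.
#' @export
reconstruct_ghr <- function(h, settings = reconstruction_settings("ghr")) {
  if (inherits(h, "hologram_stack")) {
    if (length(h$frames) != 1L)
      stop("reconstruct_ghr: pass a single hologram (or 1-frame stack)", call. = FALSE)
    h <- h$frames[[1]]
  }
  stopifnot(inherits(h, "hologram"))
  a <- normalize_hologram(h, settings$hologram_to_amplitude)
  u <- field_from_amplitude(a, h$grid, h$wavelength, plane_tag = "camera")
  out <- propagate(u, -h$distance, pad_factor = settings$pad_factor)
  out$plane_tag <- "object"
  out
}

substitute_amplitude <- function(values, amplitude) {
  amplitude * exp(1i * Arg(values))
}

#' Multi-frame Gerchberg-Saxton phase retrieval (GS)
#'
#' Alternating projections between the measurement planes: starting from the
#' first frame's amplitude with zero phase, the field is propagated to each
#' hologram plane in listed order and its amplitude replaced by the measured
#' one while keeping the phase; after `iterations` full cycles it is
#' backpropagated to the object plane. In wavelength multiplexing every
#' inter-frame transfer passes through the object plane, where the phase
#' estimate is rescaled between wavelengths with
#' [rescale_phase_wavelength()] (the optical path difference, not the phase,
#' is wavelength-invariant).
#'
#' Iterating suppresses the twin image on clean data, but on shot-noisy data
#' the iteration fits the uncorrelated noise and the error grows with `T`.
#'
#' @param stack A [hologram_stack()] (>= 2 distinct planes for real phase
#'   diversity; a single frame degenerates to [reconstruct_ghr()]).
#' @param settings A [reconstruction_settings()].
#' @param trace_truth Optional amplitude (or phase, see `trace_what`) matrix
#'   of the ground truth; when given, the object-plane RMS error is recorded
#'   after every full cycle and attached as attribute `"rms_trace"`.
#' @param trace_what `"amplitude"` or `"phase"`: which map the trace compares.
#' @return A [complex_field()] at the object plane (first frame's wavelength
#'   in wavelength mode).
#' @export
reconstruct_gs <- function(stack, settings = reconstruction_settings("gs"),
                           trace_truth = NULL,
                           trace_what = c("amplitude", "phase")) {
  stopifnot(inherits(stack, "hologram_stack"))
  trace_what <- match.arg(trace_what)
  amps <- frame_amplitudes(stack, settings$hologram_to_amplitude)
  z <- stack_distances(stack)
  lam <- stack_wavelengths(stack)
  K <- length(amps)
  if (stack$multiplex_mode == "distance" && K > 1L &&
      length(unique(z)) < 2L)
    stop("reconstruct_gs: need >= 2 distinct planes in distance mode", call. = FALSE)
  g <- stack$grid
  pad <- settings$pad_factor
  trace <- if (is.null(trace_truth)) NULL else numeric(settings$iterations)

  if (stack$multiplex_mode == "distance") {
    u <- field_from_amplitude(amps[[1]], g, lam[1], plane_tag = "camera")
    cur <- z[1]
    for (t in seq_len(settings$iterations)) {
      for (k in seq_len(K)) {
        if (z[k] != cur) {
          u <- propagate(u, z[k] - cur, pad_factor = pad)
          cur <- z[k]
        }
        u$values <- substitute_amplitude(u$values, amps[[k]])
      }
      if (!is.null(trace)) {
        uo <- propagate(u, -cur, pad_factor = pad)
        est <- if (trace_what == "amplitude") Mod(uo$values) else Arg(uo$values)
        trace[t] <- rms_error(est, trace_truth,
                              piston = (trace_what == "phase"))
      }
    }
    out <- propagate(u, -cur, pad_factor = pad)
  } else {
    zs <- z[1]
    u <- field_from_amplitude(amps[[1]], g, lam[1], plane_tag = "camera")
    cur_lam <- lam[1]
    for (t in seq_len(settings$iterations)) {
      for (k in seq_len(K)) {
        if (lam[k] != cur_lam) {
          uo <- propagate(u, -zs, pad_factor = pad)
          uo <- rescale_phase_wavelength(uo, lam[k])
          u <- propagate(uo, +zs, pad_factor = pad)
          cur_lam <- lam[k]
        }
        u$values <- substitute_amplitude(u$values, amps[[k]])
      }
      if (!is.null(trace)) {
        uo <- rescale_phase_wavelength(propagate(u, -zs, pad_factor = pad), lam[1])
        est <- if (trace_what == "amplitude") Mod(uo$values) else Arg(uo$values)
        trace[t] <- rms_error(est, trace_truth,
                              piston = (trace_what == "phase"))
      }
    }
    out <- rescale_phase_wavelength(propagate(u, -zs, pad_factor = pad), lam[1])
  }
  out$plane_tag <- "object"
  if (!is.null(trace)) attr(out, "rms_trace") <- trace
  out
}

#' Gabor averaging (GA)
#'
#' Backpropagates every frame independently (as in [reconstruct_ghr()]) and
#' averages the complex fields at the object plane. The in-focus object term
#' is identical in every frame while shot noise (and part of the twin image)
#' is uncorrelated, so averaging K frames reduces the background noise
#' standard deviation by about `1/sqrt(K)`. In wavelength mode each term is
#' phase-rescaled to the first frame's wavelength before averaging.
#'
#' @param stack A [hologram_stack()] (>= 1 frame; repeated distances allowed).
#' @param settings A [reconstruction_settings()].
#' @return A [complex_field()] at the object plane.
#' @export
reconstruct_ga <- function(stack, settings = reconstruction_settings("ga")) {
  stopifnot(inherits(stack, "hologram_stack"))
  amps <- frame_amplitudes(stack, settings$hologram_to_amplitude)
  z <- stack_distances(stack)
  lam <- stack_wavelengths(stack)
  g <- stack$grid
  acc <- matrix(0 + 0i, g$rows, g$cols)
  for (k in seq_along(amps)) {
    u <- field_from_amplitude(amps[[k]], g, lam[k], plane_tag = "camera")
    uo <- propagate(u, -z[k], pad_factor = settings$pad_factor)
    if (lam[k] != lam[1]) uo <- rescale_phase_wavelength(uo, lam[1])
    acc <- acc + uo$values
  }
  out <- complex_field(acc / length(amps), g, lam[1], plane_tag = "object")
  out
}

#' Iterative Gabor averaging (IGA)
#'
#' Hybrid reconstruction that routes each spatial-frequency band to the
#' algorithm that handles it best. Twin-image disturbance concentrates at
#' low spatial frequencies while shot noise is broadband, so:
#' \enumerate{
#'   \item each recorded intensity image is Gaussian low-pass filtered
#'     (std `sigma` pixels) and the filtered stack is reconstructed with
#'     [reconstruct_gs()] (`iterations` cycles) -- twin-image-free but
#'     blurred (`U_LP`);
#'   \item the raw stack is reconstructed with [reconstruct_ga()] and the
#'     resulting complex field is high-pass filtered with the same kernel --
#'     sharp, shot-noise-averaged high frequencies (`U_HP`);
#' }
#' and the output is the complex sum `U_LP + U_HP`. Larger `sigma` shifts
#' weight toward the noise-robust GA path at the cost of weaker twin-image
#' suppression.
#'
#' @param stack A [hologram_stack()] with >= 2 frames.
#' @param settings A [reconstruction_settings()]; `sigma` and `iterations`
#'   are the two tuning parameters.
#' @return A [complex_field()] at the object plane.
#' @export
reconstruct_iga <- function(stack, settings = reconstruction_settings("iga")) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (length(stack$frames) < 2L)
    stop("reconstruct_iga: need at least 2 frames", call. = FALSE)
  if (!is.finite(settings$sigma) || settings$sigma <= 0)
    stop("reconstruct_iga: sigma must be > 0", call. = FALSE)
  lp_frames <- lapply(stack$frames, function(f) {
    fi <- pmax(gaussian_lowpass(f$intensity, settings$sigma), 0)
    hologram(fi, f$distance, f$wavelength, f$grid, f$acquisition)
  })
  lp_stack <- hologram_stack(lp_frames, stack$multiplex_mode)
  u_lp <- reconstruct_gs(lp_stack, settings)
  if (settings$strict_band) u_lp <- gaussian_lowpass(u_lp, settings$sigma)
  u_ga <- reconstruct_ga(stack, settings)
  u_hp <- gaussian_highpass(u_ga, settings$sigma)
  out <- u_lp
  out$values <- u_lp$values + u_hp$values
  out$plane_tag <- "object"
  out
}

#' Rescale a field's phase to another wavelength
#'
#' At the object plane the phase encodes the optical path difference,
#' `phi = 2 pi OPD / lambda`, so a phase map measured at one wavelength maps
#' to another as `phi' = phi * lambda / lambda_target`. The amplitude is
#' preserved and the field's wavelength tag updated.
#'
#' @param field A [complex_field()] at the object plane.
#' @param target_wavelength Wavelength (m) to express the phase at, > 0.
#' @return A [complex_field()] at `target_wavelength`.
#' @export
rescale_phase_wavelength <- function(field, target_wavelength) {
  stopifnot(is_complex_field(field))
  if (!is.numeric(target_wavelength) || target_wavelength <= 0)
    stop("rescale_phase_wavelength: target_wavelength must be > 0", call. = FALSE)
  ph <- Arg(field$values) * (field$wavelength / target_wavelength)
  out <- field
  out$values <- Mod(field$values) * exp(1i * ph)
  out$wavelength <- target_wavelength
  out
}

#' Reconstruct a hologram stack with the method named in the settings
#'
#' Front-end dispatching to [reconstruct_ghr()] (first frame),
#' [reconstruct_gs()], [reconstruct_ga()] or [reconstruct_iga()].
#'
#' @param stack A [hologram_stack()] (or a [hologram()] for `"ghr"`).
#' @param settings A [reconstruction_settings()].
#' @param ... Passed on to the method (e.g. `trace_truth` for GS).
#' @return A [complex_field()] at the object plane.
#' @export
reconstruct <- function(stack, settings = reconstruction_settings(), ...) {
  switch(settings$method,
         ghr = reconstruct_ghr(if (inherits(stack, "hologram_stack"))
           stack$frames[[1]] else stack, settings),
         gs  = reconstruct_gs(stack, settings, ...),
         ga  = reconstruct_ga(stack, settings),
         iga = reconstruct_iga(stack, settings))
}
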