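#' Noise specification for simulated acquisitions
#'
#' Noise is parameterized by its standard deviation at unit mean intensity.
#' Poisson (shot) noise with `target_std = s` corresponds to a photon budget
#' of `N = 1/s^2` photons per pixel at unit intensity: the recorded value is
#' `Poisson(I * N) / N`, whose standard deviation at `I = 1` is exactly `s`.
#'
#' @param kind `"none"`, `"gaussian"` or `"poisson"`.
#' @param target_std Noise standard deviation at unit mean intensity (a.u.).
#' @param seed Optional integer seed; frame-level draws derive distinct
#'   sub-seeds deterministically from it.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "poisson"),
                       target_std = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(target_std) || length(target_std) != 1L ||
      !is.finite(target_std) || target_std < 0)
    stop("noise_spec: target_std must be a finite number >= 0", call. = FALSE)
  if (kind == "none" && target_std > 0)
    stop("noise_spec: target_std > 0 is meaningless with kind = 'none'", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(kind = kind, target_std = target_std, seed = seed),
            class = "noise_spec")
}

#' Camera model: gain, exposure and quantization
#'
#' @param bit_depth Integer in `[1, 16]`; gray levels span
#'   `[0, 2^bit_depth - 1]`.
#' @param gain Arbitrary-units-to-gray-level scale.
#' @param exposure_scale Dimensionless multiplier standing in for exposure
#'   time times irradiance.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(bit_depth = 8L, gain = 1, exposure_scale = 1) {
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 16L)
    stop("camera_model: bit_depth must be in [1, 16]", call. = FALSE)
  if (gain <= 0 || exposure_scale <= 0)
    stop("camera_model: gain and exposure_scale must be > 0", call. = FALSE)
  structure(list(bit_depth = bit_depth, gain = gain,
                 exposure_scale = exposure_scale),
            class = "camera_model")
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-frame sub-seed from a master seed (kept below 2^31).
frame_subseed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed %% 2147483629L) * 48271 + k * 2654435) %% 2147483629)
}

#' Apply camera shot noise to an intensity image
#'
#' Gaussian: adds i.i.d. `N(0, target_std^2)`. Poisson: draws
#' `Poisson(I / target_std^2) * target_std^2`, i.e. a photon budget of
#' `1/target_std^2` photons per unit intensity, so the standard deviation at
#' unit mean equals `target_std`.
#'
#' @param intensity Nonnegative numeric matrix (a.u.).
#' @param noise A [noise_spec()].
#' @return Matrix of the same shape.
#' @export
add_shot_noise <- function(intensity, noise) {
  stopifnot(is.matrix(intensity))
  if (any(intensity < 0)) stop("add_shot_noise: intensity must be >= 0", call. = FALSE)
  if (!inherits(noise, "noise_spec")) stop("add_shot_noise: need a noise_spec", call. = FALSE)
  if (noise$kind == "none" || noise$target_std == 0) return(intensity)
  with_seed(noise$seed, {
    if (noise$kind == "gaussian") {
      intensity + matrix(stats::rnorm(length(intensity), 0, noise$target_std),
                         nrow(intensity))
    } else {
      n_photons <- 1 / noise$target_std^2
      matrix(stats::rpois(length(intensity), intensity * n_photons) / n_photons,
             nrow(intensity))
    }
  })
}

#' Quantize an intensity image to camera gray levels
#'
#' `DN = clip(round(I * gain * exposure_scale), 0, 2^bit_depth - 1)`.
#'
#' @param intensity Nonnegative numeric matrix.
#' @param camera A [camera_model()].
#' @return Integer-valued matrix of digital numbers.
#' @export
quantize <- function(intensity, camera) {
  stopifnot(is.matrix(intensity), inherits(camera, "camera_model"))
  if (any(intensity < 0)) stop("quantize: intensity must be >= 0", call. = FALSE)
  dn <- round(intensity * camera$gain * camera$exposure_scale)
  pmin(pmax(dn, 0), 2^camera$bit_depth - 1)
}

#' Recorded in-line hologram
#'
#' A real nonnegative intensity image together with the acquisition metadata
#' needed to backpropagate it: sample-to-camera distance, illumination
#' wavelength and the sampling grid.
#'
#' @param intensity Nonnegative finite numeric matrix (a.u. or camera gray
#'   levels).
#' @param distance Sample-to-camera distance in meters, > 0.
#' @param wavelength Illumination wavelength in meters, > 0.
#' @param grid A [grid_spec()].
#' @param acquisition Optional list of provenance metadata (e.g. a
#'   [camera_model()], noise settings, file paths).
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, distance, wavelength, grid, acquisition = NULL) {
  stopifnot(is.matrix(intensity), is_grid_spec(grid))
  if (!all(dim(intensity) == c(grid$rows, grid$cols)))
    stop("hologram: intensity does not match grid", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("hologram: intensity must be finite and >= 0", call. = FALSE)
  if (distance <= 0) stop("hologram: distance must be > 0", call. = FALSE)
  if (wavelength <= 0) stop("hologram: wavelength must be > 0", call. = FALSE)
  structure(list(intensity = intensity, distance = distance,
                 wavelength = wavelength, grid = grid,
                 acquisition = acquisition),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, z = %.3g mm, lambda = %.1f nm, M = %.4g\n",
              x$grid$rows, x$grid$cols, x$distance * 1e3, x$wavelength * 1e9,
              mean(x$intensity)))
  invisible(x)
}

#' Multi-frame hologram stack
#'
#' An ordered list of [hologram()] frames sharing one grid. In `"distance"`
#' multiplexing all frames share the wavelength and differ in defocus
#' distance; in `"wavelength"` multiplexing all frames share the distance
#' and carry distinct wavelengths. Repeated distances are allowed (e.g. for
#' plain frame averaging); iterative phase retrieval additionally requires
#' at least two distinct planes, checked in [reconstruct_gs()].
#'
#' @param frames List of [hologram()] objects (>= 1).
#' @param multiplex_mode `"distance"` or `"wavelength"`.
#' @return An object of class `hologram_stack`.
#' @export
hologram_stack <- function(frames, multiplex_mode = c("distance", "wavelength")) {
  multiplex_mode <- match.arg(multiplex_mode)
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "hologram")))
    stop("hologram_stack: frames must be a nonempty list of holograms", call. = FALSE)
  g <- frames[[1]]$grid
  if (!all(vapply(frames, function(f) same_grid(f$grid, g), logical(1))))
    stop("hologram_stack: all frames must share one grid", call. = FALSE)
  lam <- vapply(frames, `[[`, numeric(1), "wavelength")
  z <- vapply(frames, `[[`, numeric(1), "distance")
  if (multiplex_mode == "distance") {
    if (length(unique(lam)) != 1L)
      stop("hologram_stack: distance mode requires a single wavelength", call. = FALSE)
  } else {
    if (length(unique(z)) != 1L)
      stop("hologram_stack: wavelength mode requires a single distance", call. = FALSE)
    if (anyDuplicated(lam))
      stop("hologram_stack: wavelength mode requires distinct wavelengths", call. = FALSE)
  }
  structure(list(frames = frames, multiplex_mode = multiplex_mode, grid = g),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  cat(sprintf("<hologram_stack> %d frame(s), %s-multiplexed, %d x %d px\n",
              length(x$frames), x$multiplex_mode, x$grid$rows, x$grid$cols))
  for (f in x$frames)
    cat(sprintf("  z = %.3g mm, lambda = %.1f nm\n",
                f$distance * 1e3, f$wavelength * 1e9))
  invisible(x)
}

stack_distances <- function(stack) vapply(stack$frames, `[[`, numeric(1), "distance")
stack_wavelengths <- function(stack) vapply(stack$frames, `[[`, numeric(1), "wavelength")

#' Simulate the recording of one in-line hologram
#'
#' Builds the object transmittance at the illumination wavelength
#' (`U0 = amplitude * exp(i * phase * reference_wavelength / wavelength)`,
#' keeping the optical path difference fixed), propagates it to the camera
#' plane and records the intensity under unit illumination, then applies
#' shot noise ([add_shot_noise()]) and, when a camera is supplied,
#' quantization ([quantize()]).
#'
#' @param object A [synthetic_object()].
#' @param distance Sample-to-camera distance (m), > 0.
#' @param wavelength Illumination wavelength (m).
#' @param noise A [noise_spec()] (default: noise-free).
#' @param camera Optional [camera_model()]; when given, the output intensity
#'   is in integer gray levels.
#' @param pad_factor Padding used in the forward propagation; the default 1
#'   keeps the uniform background exactly uniform (periodic boundary).
#' @return A [hologram()].
#' @export
record_hologram <- function(object, distance, wavelength = 500e-9,
                            noise = noise_spec("none"), camera = NULL,
                            pad_factor = 1L) {
  stopifnot(inherits(object, "synthetic_object"))
  if (distance <= 0) stop("record_hologram: distance must be > 0", call. = FALSE)
  u0 <- complex_field(object$amplitude *
                        exp(1i * object$phase * object$reference_wavelength / wavelength),
                      object$grid, wavelength, plane_tag = "object")
  cam_field <- propagate(u0, +distance, pad_factor = pad_factor)
  intensity <- field_intensity(cam_field)
  intensity <- add_shot_noise(pmax(intensity, 0), noise)
  if (!is.null(camera)) intensity <- quantize(pmax(intensity, 0), camera)
  hologram(pmax(intensity, 0), distance, wavelength, object$grid,
           acquisition = list(camera = camera, noise_kind = noise$kind,
                              noise_std = noise$target_std, seed = noise$seed,
                              provenance = "simulated"))
}

#' Simulate a multiplexed hologram stack
#'
#' One [record_hologram()] per frame with independent noise draws: each frame
#' uses a distinct sub-seed derived deterministically from `noise$seed`, so
#' stacks are reproducible while frames stay independent.
#'
#' @param object A [synthetic_object()].
#' @param distances Vector of distances (m) for distance multiplexing
#'   (shared `wavelength`), or a single shared distance when `wavelengths`
#'   is given.
#' @param wavelengths Optional vector of wavelengths (m) for wavelength
#'   multiplexing.
#' @param wavelength Shared wavelength (m) in distance mode.
#' @param noise A [noise_spec()] applied per frame.
#' @param camera Optional [camera_model()].
#' @param pad_factor Passed to [record_hologram()].
#' @return A [hologram_stack()].
#' @examples
#' g <- grid_spec(64, 64, 2e-6)
#' obj <- make_text_phase_object("Q", g)
#' st <- record_stack(obj, distances = c(2e-3, 3e-3, 4e-3))
#' @export
record_stack <- function(object, distances = NULL, wavelengths = NULL,
                         wavelength = 500e-9, noise = noise_spec("none"),
                         camera = NULL, pad_factor = 1L) {
  stopifnot(inherits(object, "synthetic_object"))
  if (is.null(wavelengths)) {
    if (is.null(distances) || length(distances) < 1L)
      stop("record_stack: give distances or wavelengths", call. = FALSE)
    frames <- lapply(seq_along(distances), function(k) {
      nk <- noise; nk$seed <- frame_subseed(noise$seed, k)
      record_hologram(object, distances[k], wavelength, nk, camera, pad_factor)
    })
    hologram_stack(frames, "distance")
  } else {
    if (is.null(distances) || length(distances) != 1L)
      stop("record_stack: wavelength mode needs a single shared distance", call. = FALSE)
    frames <- lapply(seq_along(wavelengths), function(k) {
      nk <- noise; nk$seed <- frame_subseed(noise$seed, k)
      record_hologram(object, distances, wavelengths[k], nk, camera, pad_factor)
    })
    hologram_stack(frames, "wavelength")
  }
}
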