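# Affine [0,1] packing for float TIFF storage (libtiff float samples are
# stored in [0,1] by the tiff package); scale/offset live in the manifest so
# the round trip is lossless at float32 precision.
pack_unit <- function(x) {
  off <- min(x)
  sc <- max(x) - off
  if (sc == 0) sc <- 1
  list(data = (x - off) / sc, offset = off, scale = sc)
}

write_gray_tiff <- function(x, path, bits = 32L) {
  if (bits == 32L) {
    p <- pack_unit(x)
    suppressWarnings(tiff::writeTIFF(p$data, path, bits.per.sample = 32L))
    list(dtype = "float32", offset = p$offset, scale = p$scale)
  } else {
    maxdn <- 2^bits - 1
    if (any(x < 0) || any(x > maxdn) || any(x != round(x)))
      stop("write_gray_tiff: integer mode needs integer gray levels in range",
           call. = FALSE)
    suppressWarnings(tiff::writeTIFF(x / maxdn, path, bits.per.sample = as.integer(bits)))
    list(dtype = paste0("uint", bits), offset = 0, scale = 1)
  }
}

#' Read a grayscale image preserving gray-level units
#'
#' TIFF and PNG images are decoded to a numeric matrix *without* rescaling:
#' integer images keep their digital numbers (an 8-bit PNG with maximum
#' value 255 reads back with maximum 255.0), float TIFFs keep their stored
#' values.
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @param channel For multi-channel images, which channel to extract
#'   (`NULL` = require single-channel).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("read_gray_image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    # 8/16-bit integer samples are decoded to [0,1]: undo that to keep gray
    # levels; 32-bit samples are float and come back as stored
    if (!is.null(bits) && bits %in% c(8L, 16L)) img <- img * (2^bits - 1)
    img <- strip_attrs(img)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    img <- strip_attrs(img * (2^depth - 1))
  } else stop("read_gray_image: unsupported format: ", ext, call. = FALSE)
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("read_gray_image: image has ", dim(img)[3],
           " channels; pass `channel`", call. = FALSE)
    img <- img[, , channel]
  }
  img
}

strip_attrs <- function(x) {
  d <- dim(x)
  attributes(x) <- NULL
  dim(x) <- d
  x
}

#' Write a hologram stack to disk
#'
#' One TIFF per frame (32-bit float, or 8/16-bit integer for quantized
#' camera data) plus a JSON manifest recording geometry in SI units,
#' multiplex mode, per-frame scale/offset and camera metadata.
#'
#' @param stack A [hologram_stack()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the frame files and manifest.
#' @return Path of the written manifest (invisibly).
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, dir, name = "stack") {
  stopifnot(inherits(stack, "hologram_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- vector("list", length(stack$frames))
  for (k in seq_along(stack$frames)) {
    f <- stack$frames[[k]]
    fname <- sprintf("%s_frame%02d.tif", name, k)
    cam <- f$acquisition$camera
    bits <- if (!is.null(cam) && all(f$intensity == round(f$intensity)) &&
                max(f$intensity) <= 2^16 - 1) {
      if (cam$bit_depth <= 8L) 8L else 16L
    } else 32L
    meta <- write_gray_tiff(f$intensity, file.path(dir, fname), bits)
    frames[[k]] <- c(list(path = fname, distance_m = f$distance,
                          wavelength_m = f$wavelength), meta)
  }
  cam <- stack$frames[[1]]$acquisition$camera
  manifest <- list(
    pixel_pitch_m = stack$grid$pitch,
    multiplex_mode = stack$multiplex_mode,
    frames = frames,
    camera = if (!is.null(cam)) list(bit_depth = cam$bit_depth) else NULL
  )
  mpath <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mpath)
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop(sprintf("read_stack: manifest is missing field '%s' (%s)", field, where),
         call. = FALSE)
  x[[field]]
}

#' Read a hologram stack from a JSON manifest
#'
#' The manifest lists per-frame image paths (relative to the manifest
#' location), distances and wavelengths in meters, the pixel pitch, and the
#' multiplex mode; see [write_stack()] for the schema. Images are decoded
#' without rescaling (float frames have their stored scale/offset
#' reapplied).
#'
#' @param manifest_path Path to the JSON manifest.
#' @return A [hologram_stack()].
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("read_stack: no such manifest: ", manifest_path, call. = FALSE)
  man <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  pitch <- need_field(man, "pixel_pitch_m", "top level")
  mode <- need_field(man, "multiplex_mode", "top level")
  fr <- need_field(man, "frames", "top level")
  frames <- lapply(seq_along(fr), function(k) {
    e <- fr[[k]]
    where <- sprintf("frame %d", k)
    path <- file.path(base, need_field(e, "path", where))
    z <- need_field(e, "distance_m", where)
    lam <- need_field(e, "wavelength_m", where)
    img <- read_gray_image(path)
    sc <- if (!is.null(e$scale)) e$scale else 1
    off <- if (!is.null(e$offset)) e$offset else 0
    if (identical(e$dtype, "float32")) img <- img * sc + off
    g <- grid_spec(nrow(img), ncol(img), pitch)
    hologram(img, z, lam, g,
             acquisition = list(provenance = paste0("file:", path)))
  })
  shapes <- vapply(frames, function(f) paste(dim(f$intensity), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("read_stack: frames decode to different shapes", call. = FALSE)
  hologram_stack(frames, mode)
}

#' Split an RGB image into a wavelength-multiplexed stack
#'
#' Treats each color channel of an RGB snapshot as an in-line hologram
#' recorded at its own illumination wavelength (defaults 450/532/635 nm),
#' all sharing one defocus distance.
#'
#' @param path 3-channel TIFF or PNG image.
#' @param distance Shared defocus distance (m).
#' @param pitch Pixel pitch (m).
#' @param wavelengths Per-channel wavelengths (m), in R, G, B order.
#' @return A wavelength-multiplexed [hologram_stack()].
#' @export
split_rgb <- function(path, distance, pitch,
                      wavelengths = c(450e-9, 532e-9, 635e-9)) {
  if (length(wavelengths) != 3L)
    stop("split_rgb: need exactly 3 wavelengths", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 16L)) x <- x * (2^bits - 1)
    strip_attrs(x)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    strip_attrs(x * (2^depth - 1))
  } else stop("split_rgb: unsupported format: ", ext, call. = FALSE)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("split_rgb: image must have 3 channels", call. = FALSE)
  g <- grid_spec(dim(img)[1], dim(img)[2], pitch)
  frames <- lapply(1:3, function(k)
    hologram(img[, , k], distance, wavelengths[k], g,
             acquisition = list(provenance = sprintf("file:%s channel %d", path, k))))
  hologram_stack(frames, "wavelength")
}

#' Write a reconstructed field (phase + amplitude) to disk
#'
#' 32-bit float TIFFs for the phase and amplitude maps plus a JSON sidecar
#' carrying the scale/offset needed to restore them and any provenance
#' supplied (method, iterations, sigma, input hashes, ...).
#'
#' @param field A [complex_field()].
#' @param dir Output directory.
#' @param name Basename.
#' @param provenance Named list stored verbatim in the sidecar.
#' @return Path of the sidecar JSON (invisibly).
#' @export
write_field <- function(field, dir, name = "reconstruction", provenance = list()) {
  stopifnot(is_complex_field(field))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- sprintf("%s_phase.tif", name)
  ap <- sprintf("%s_amplitude.tif", name)
  mp <- write_gray_tiff(field_phase(field), file.path(dir, pp), 32L)
  ma <- write_gray_tiff(field_amplitude(field), file.path(dir, ap), 32L)
  sidecar <- list(
    phase = c(list(path = pp), mp),
    amplitude = c(list(path = ap), ma),
    wavelength_m = field$wavelength,
    pixel_pitch_m = field$grid$pitch,
    plane = field$plane_tag,
    provenance = provenance
  )
  spath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, spath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(spath)
}

#' Read a field written by [write_field()]
#'
#' @param sidecar_path The sidecar JSON.
#' @return A [complex_field()].
#' @export
read_field <- function(sidecar_path) {
  sc <- jsonlite::read_json(sidecar_path)
  base <- dirname(sidecar_path)
  restore <- function(e) {
    img <- read_gray_image(file.path(base, e$path))
    img * e$scale + e$offset
  }
  ph <- restore(sc$phase)
  am <- restore(sc$amplitude)
  g <- grid_spec(nrow(ph), ncol(ph), sc$pixel_pitch_m)
  complex_field(am * exp(1i * ph), g, sc$wavelength_m,
                plane_tag = if (!is.null(sc$plane)) sc$plane else "unspecified")
}
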