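#' Complex optical field
#'
#' The object of propagation and the output of every reconstructor: a 2-D
#' complex-valued array sampled on a [grid_spec()], together with the
#' illumination wavelength and a free-text tag naming the axial plane the
#' field lives in (e.g. `"object"`, `"camera z=3mm"`).
#'
#' @param values Complex (or numeric) matrix; all entries must be finite.
#' @param grid A [grid_spec()] matching `dim(values)`.
#' @param wavelength Illumination wavelength in meters, > 0.
#' @param plane_tag Free-text label of the axial plane.
#' @return An object of class `complex_field`.
#' @seealso [field_from_amplitude()], [propagate()]
#' @export
complex_field <- function(values, grid, wavelength, plane_tag = "unspecified") {
  if (!is.matrix(values)) stop("complex_field: values must be a matrix", call. = FALSE)
  if (!is_grid_spec(grid)) stop("complex_field: grid must be a grid_spec", call. = FALSE)
  if (nrow(values) != grid$rows || ncol(values) != grid$cols)
    stop("complex_field: values dimensions do not match grid", call. = FALSE)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("complex_field: values must be finite", call. = FALSE)
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("complex_field: wavelength must be a positive number (meters)", call. = FALSE)
  structure(list(values = values, grid = grid, wavelength = wavelength,
                 plane_tag = as.character(plane_tag)),
            class = "complex_field")
}

is_complex_field <- function(x) inherits(x, "complex_field")

#' Lift a real amplitude image to a zero-phase complex field
#'
#' Used to turn a measured hologram amplitude into a [complex_field()] ready
#' for numerical backpropagation (the recorded hologram carries no phase).
#'
#' @param amplitude Nonnegative, finite numeric matrix.
#' @inheritParams complex_field
#' @return A `complex_field` with `|values| == amplitude` and phase 0.
#' @export
field_from_amplitude <- function(amplitude, grid, wavelength,
                                 plane_tag = "unspecified") {
  if (!is.matrix(amplitude) || !is.numeric(amplitude))
    stop("field_from_amplitude: amplitude must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(amplitude)))
    stop("field_from_amplitude: amplitude must be finite", call. = FALSE)
  if (any(amplitude < 0))
    stop("field_from_amplitude: amplitude must be nonnegative", call. = FALSE)
  complex_field(amplitude + 0i, grid, wavelength, plane_tag)
}

#' Amplitude and phase of a complex field
#'
#' @param field A [complex_field()].
#' @return `field_amplitude()`: matrix of `|U|`; `field_phase()`: matrix of
#'   `Arg(U)` in `(-pi, pi]`; `field_intensity()`: matrix of `|U|^2`.
#' @export
field_amplitude <- function(field) {
  stopifnot(is_complex_field(field))
  Mod(field$values)
}

#' @rdname field_amplitude
#' @export
field_phase <- function(field) {
  stopifnot(is_complex_field(field))
  Arg(field$values)
}

#' @rdname field_amplitude
#' @export
field_intensity <- function(field) {
  stopifnot(is_complex_field(field))
  Mod(field$values)^2
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px, lambda %.1f nm, plane '%s'\n",
              x$grid$rows, x$grid$cols, x$wavelength * 1e9, x$plane_tag))
  invisible(x)
}

#' Raster plot of a complex field
#'
#' @param object A [complex_field()].
#' @param what `"phase"`, `"amplitude"` or `"intensity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot complex_field
#' @export
autoplot.complex_field <- function(object, what = c("phase", "amplitude", "intensity"),
                                   ...) {
  what <- match.arg(what)
  m <- switch(what,
              phase = field_phase(object),
              amplitude = field_amplitude(object),
              intensity = field_intensity(object))
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column [px]", y = "row [px]")
}
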