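#' Sampling grid of a camera or field
#'
#' A `grid_spec` describes the discrete sampling of every image in the
#' package: number of rows and columns and the physical pixel pitch in
#' meters. All physical conversions (spatial frequencies, propagation
#' kernels) go through the pitch; unit magnification is assumed, so for a
#' lens-based system the pitch is the *effective* (demagnified) pixel size.
#'
#' @param rows,cols Integer image dimensions, each at least 2.
#' @param pitch Physical sampling interval in meters (pixel size).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(256, 256, pitch = 2e-6)
#' @export
grid_spec <- function(rows, cols, pitch) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 2L || cols < 2L)
    stop("grid_spec: rows and cols must be integers >= 2", call. = FALSE)
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("grid_spec: pitch must be a positive finite number (meters)", call. = FALSE)
  structure(list(rows = rows, cols = cols, pitch = pitch), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, pitch %.3g um\n",
              x$rows, x$cols, x$pitch * 1e6))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

same_grid <- function(a, b) {
  a$rows == b$rows && a$cols == b$cols &&
    isTRUE(all.equal(a$pitch, b$pitch, tolerance = 1e-12))
}

# DFT frequencies in cycles per meter, standard layout (zero frequency first).
# Delta f = 1/(n * pitch).
fft_freq <- function(n, pitch) {
  k <- c(0:((n - 1) %/% 2), -((n) %/% 2):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  k / (n * pitch)
}

# Squared radial frequency grid (rows x cols) on the DFT layout.
freq_sq_grid <- function(rows, cols, pitch) {
  fy <- fft_freq(rows, pitch)
  fx <- fft_freq(cols, pitch)
  outer(fy^2, fx^2, `+`)
}
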