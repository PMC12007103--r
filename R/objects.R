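# 5x7 bitmap glyphs (each row a 5-bit integer, MSB = left column). Rendered
# by pure arithmetic so object artwork is byte-identical across platforms.
.glyph5x7 <- list(
  "A" = c(0x0E,0x11,0x11,0x1F,0x11,0x11,0x11),
  "B" = c(0x1E,0x11,0x11,0x1E,0x11,0x11,0x1E),
  "C" = c(0x0E,0x11,0x10,0x10,0x10,0x11,0x0E),
  "D" = c(0x1E,0x11,0x11,0x11,0x11,0x11,0x1E),
  "E" = c(0x1F,0x10,0x10,0x1E,0x10,0x10,0x1F),
  "F" = c(0x1F,0x10,0x10,0x1E,0x10,0x10,0x10),
  "G" = c(0x0E,0x11,0x10,0x17,0x11,0x11,0x0F),
  "H" = c(0x11,0x11,0x11,0x1F,0x11,0x11,0x11),
  "I" = c(0x0E,0x04,0x04,0x04,0x04,0x04,0x0E),
  "J" = c(0x07,0x02,0x02,0x02,0x02,0x12,0x0C),
  "K" = c(0x11,0x12,0x14,0x18,0x14,0x12,0x11),
  "L" = c(0x10,0x10,0x10,0x10,0x10,0x10,0x1F),
  "M" = c(0x11,0x1B,0x15,0x15,0x11,0x11,0x11),
  "N" = c(0x11,0x19,0x15,0x13,0x11,0x11,0x11),
  "O" = c(0x0E,0x11,0x11,0x11,0x11,0x11,0x0E),
  "P" = c(0x1E,0x11,0x11,0x1E,0x10,0x10,0x10),
  "Q" = c(0x0E,0x11,0x11,0x11,0x15,0x12,0x0D),
  "R" = c(0x1E,0x11,0x11,0x1E,0x14,0x12,0x11),
  "S" = c(0x0F,0x10,0x10,0x0E,0x01,0x01,0x1E),
  "T" = c(0x1F,0x04,0x04,0x04,0x04,0x04,0x04),
  "U" = c(0x11,0x11,0x11,0x11,0x11,0x11,0x0E),
  "V" = c(0x11,0x11,0x11,0x11,0x11,0x0A,0x04),
  "W" = c(0x11,0x11,0x11,0x15,0x15,0x1B,0x11),
  "X" = c(0x11,0x11,0x0A,0x04,0x0A,0x11,0x11),
  "Y" = c(0x11,0x11,0x0A,0x04,0x04,0x04,0x04),
  "Z" = c(0x1F,0x01,0x02,0x04,0x08,0x10,0x1F),
  "0" = c(0x0E,0x11,0x13,0x15,0x19,0x11,0x0E),
  "1" = c(0x04,0x0C,0x04,0x04,0x04,0x04,0x0E),
  "2" = c(0x0E,0x11,0x01,0x06,0x08,0x10,0x1F),
  "3" = c(0x1F,0x01,0x02,0x06,0x01,0x11,0x0E),
  "4" = c(0x02,0x06,0x0A,0x12,0x1F,0x02,0x02),
  "5" = c(0x1F,0x10,0x1E,0x01,0x01,0x11,0x0E),
  "6" = c(0x06,0x08,0x10,0x1E,0x11,0x11,0x0E),
  "7" = c(0x1F,0x01,0x02,0x04,0x08,0x08,0x08),
  "8" = c(0x0E,0x11,0x11,0x0E,0x11,0x11,0x0E),
  "9" = c(0x0E,0x11,0x11,0x0F,0x01,0x02,0x0C),
  " " = c(0,0,0,0,0,0,0)
)

glyph_matrix <- function(ch) {
  rows <- .glyph5x7[[toupper(ch)]]
  if (is.null(rows))
    stop(sprintf("no glyph for character '%s'", ch), call. = FALSE)
  m <- matrix(0, 7, 5)
  for (r in 1:7) m[r, ] <- as.integer(bitwAnd(rows[r], c(16L, 8L, 4L, 2L, 1L)) > 0)
  m
}

# Render `text` as a binary mask centered on a rows x cols grid; integer
# nearest-neighbour upscaling of the 5x7 glyphs, 1 px inter-glyph spacing.
render_text_mask <- function(text, rows, cols, scale = NULL) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  w_units <- 6L * n - 1L   # 5 px glyph + 1 px gap
  h_units <- 7L
  # default sizing keeps the glyph fill factor low enough that simulated
  # holograms have contrast of the same order as real thin-sample data
  if (is.null(scale))
    scale <- max(1L, floor(min(0.30 * cols / w_units, 0.35 * rows / h_units)))
  scale <- as.integer(scale)
  if (w_units * scale > cols || h_units * scale > rows)
    stop("render_text_mask: glyphs larger than grid", call. = FALSE)
  mask <- matrix(0, rows, cols)
  r0 <- (rows - h_units * scale) %/% 2
  c0 <- (cols - w_units * scale) %/% 2
  up <- function(m, s) m[rep(seq_len(nrow(m)), each = s),
                         rep(seq_len(ncol(m)), each = s), drop = FALSE]
  for (i in seq_len(n)) {
    g <- up(glyph_matrix(chars[i]), scale)
    rr <- r0 + seq_len(nrow(g))
    cc <- c0 + (i - 1L) * 6L * scale + seq_len(ncol(g))
    mask[rr, cc] <- g
  }
  mask
}

# Light anti-aliasing and exact [0, 1] support for a binary mask.
smooth_mask <- function(mask, sigma = 1) {
  m <- gaussian_lowpass(mask, sigma)
  if (max(m) > 0) m <- m / max(m)
  m[m < 1e-6] <- 0
  m[m > 1 - 1e-6] <- 1
  pmin(pmax(m, 0), 1)
}

#' Ground-truth synthetic object
#'
#' Holds the transmittance of a simulated sample: a phase map (radians, at a
#' stated reference wavelength) and an amplitude map in `[0, 1]`. The
#' wavelength-independent optical path difference view is
#' `phase * reference_wavelength / (2 pi)` (see [object_opd()]).
#'
#' @param phase Finite numeric matrix, radians at `reference_wavelength`.
#' @param amplitude Numeric matrix in `[0, 1]`, same shape.
#' @param grid A [grid_spec()].
#' @param reference_wavelength Wavelength (m) at which `phase` is stated.
#' @return An object of class `synthetic_object`.
#' @export
synthetic_object <- function(phase, amplitude, grid, reference_wavelength = 500e-9) {
  stopifnot(is.matrix(phase), is.matrix(amplitude), is_grid_spec(grid))
  if (!all(dim(phase) == c(grid$rows, grid$cols)) ||
      !all(dim(amplitude) == c(grid$rows, grid$cols)))
    stop("synthetic_object: maps must match the grid", call. = FALSE)
  if (any(!is.finite(phase))) stop("synthetic_object: phase must be finite", call. = FALSE)
  if (any(amplitude < 0) || any(amplitude > 1))
    stop("synthetic_object: amplitude must lie in [0, 1]", call. = FALSE)
  if (reference_wavelength <= 0)
    stop("synthetic_object: reference_wavelength must be > 0", call. = FALSE)
  structure(list(phase = phase, amplitude = amplitude, grid = grid,
                 reference_wavelength = reference_wavelength),
            class = "synthetic_object")
}

#' @rdname synthetic_object
#' @param object A `synthetic_object`.
#' @return `object_opd()`: matrix of optical path difference in meters.
#' @export
object_opd <- function(object) {
  stopifnot(inherits(object, "synthetic_object"))
  object$phase * object$reference_wavelength / (2 * pi)
}

#' Synthetic pure-phase text object
#'
#' Renders `text` from the built-in bitmap font, lightly smooths the binary
#' mask (1 px Gaussian anti-aliasing) and maps it so the background carries
#' `phase_min` and glyph interiors `phase_max`; the amplitude is identically
#' 1. This is the stand-in artwork for phase-object simulation studies
#' (default range -0.4 to 0.6 rad).
#'
#' @param text Nonempty string (A-Z, 0-9, space).
#' @param grid A [grid_spec()].
#' @param phase_min,phase_max Background / glyph phase in radians
#'   (`phase_min < phase_max`, or equal for an empty object).
#' @param reference_wavelength Wavelength (m) the phase refers to.
#' @param scale Optional integer glyph upscaling factor; chosen automatically
#'   to fill about 70\% of the grid width when `NULL`.
#' @return A [synthetic_object()].
#' @export
make_text_phase_object <- function(text, grid, phase_min = -0.4, phase_max = 0.6,
                                   reference_wavelength = 500e-9, scale = NULL) {
  if (!nzchar(text)) stop("make_text_phase_object: text must be nonempty", call. = FALSE)
  if (phase_min > phase_max)
    stop("make_text_phase_object: phase_min must be <= phase_max", call. = FALSE)
  mask <- smooth_mask(render_text_mask(text, grid$rows, grid$cols, scale))
  phase <- phase_min + mask * (phase_max - phase_min)
  synthetic_object(phase, matrix(1, grid$rows, grid$cols), grid,
                   reference_wavelength)
}

#' Synthetic amplitude-only object
#'
#' Absorbing features on a transmitting background: the background carries
#' `amp_max` (the unscattered reference wave an in-line hologram needs) and
#' glyph interiors `amp_min`. The phase is identically zero.
#'
#' @param pattern A string rendered with the bitmap font, or a numeric matrix
#'   mask in `[0, 1]` (1 = feature) matching the grid.
#' @param grid A [grid_spec()].
#' @param amp_min,amp_max Feature / background amplitude, both in `[0, 1]`.
#' @param reference_wavelength Reference wavelength tag (m).
#' @inheritParams make_text_phase_object
#' @return A [synthetic_object()].
#' @export
make_amplitude_object <- function(pattern, grid, amp_min = 0, amp_max = 1,
                                  reference_wavelength = 500e-9, scale = NULL) {
  if (is.character(pattern)) {
    mask <- smooth_mask(render_text_mask(pattern, grid$rows, grid$cols, scale))
  } else if (is.matrix(pattern)) {
    if (!all(dim(pattern) == c(grid$rows, grid$cols)))
      stop("make_amplitude_object: mask must match the grid", call. = FALSE)
    mask <- pmin(pmax(pattern, 0), 1)
  } else stop("make_amplitude_object: pattern must be text or a matrix", call. = FALSE)
  if (amp_min > amp_max)
    stop("make_amplitude_object: amp_min must be <= amp_max", call. = FALSE)
  amp <- amp_max + mask * (amp_min - amp_max)
  synthetic_object(matrix(0, grid$rows, grid$cols), amp, grid,
                   reference_wavelength)
}

#' Bar width rule for the synthetic resolution target
#'
#' Bar width (pixels) of element `element`, halving every 6 elements as in
#' standard three-bar resolution charts:
#' `round(base_width_px * 2^(-(element - 1)/6))`, never below 1.
#'
#' @param base_width_px Bar width of element 1 in pixels.
#' @param element Element index (1-based).
#' @return Integer bar width in pixels.
#' @export
resolution_bar_width <- function(base_width_px, element) {
  pmax(1L, as.integer(round(base_width_px * 2^(-(element - 1) / 6))))
}

#' Synthetic optically thin resolution phase target
#'
#' Three-bar groups (a vertical and a horizontal triplet per element) at a
#' uniform phase step over a zero-phase background; amplitude identically 1.
#' Element sizing follows [resolution_bar_width()].
#'
#' @param grid A [grid_spec()].
#' @param step_phase Phase of the bars in radians (>= 0).
#' @param base_width_px Bar width of the first element, pixels.
#' @param n_elements Number of elements to attempt to place (those that do
#'   not fit are dropped; at least one must fit).
#' @param reference_wavelength Wavelength (m) the phase refers to.
#' @return A [synthetic_object()].
#' @export
make_resolution_target <- function(grid, step_phase, base_width_px = 8L,
                                   n_elements = 4L,
                                   reference_wavelength = 561e-9) {
  if (step_phase < 0)
    stop("make_resolution_target: step_phase must be >= 0", call. = FALSE)
  mask <- matrix(0, grid$rows, grid$cols)
  margin <- max(2L, base_width_px)
  x <- margin + 1L
  placed <- 0L
  for (e in seq_len(n_elements)) {
    w <- resolution_bar_width(base_width_px, e)
    len <- 5L * w
    # vertical triplet on top, horizontal triplet below
    need_w <- len
    need_h <- len + w + 3L * w + 2L * w  # bars block + gap + horizontal block
    if (x + need_w - 1L > grid$cols - margin || margin + need_h > grid$rows - margin) break
    y <- margin + 1L
    for (b in 0:2) {                      # vertical bars: width w, length 5w
      cc <- x + b * 2L * w + seq_len(w) - 1L
      if (max(cc) > grid$cols) break
      mask[y + seq_len(len) - 1L, cc] <- 1
    }
    y2 <- y + len + w
    for (b in 0:2) {                      # horizontal bars
      rr <- y2 + b * 2L * w + seq_len(w) - 1L
      mask[rr, x + seq_len(len) - 1L] <- 1
    }
    placed <- placed + 1L
    x <- x + len + 2L * w
  }
  if (placed == 0L)
    stop("make_resolution_target: no element fits the grid", call. = FALSE)
  synthetic_object(step_phase * mask, matrix(1, grid$rows, grid$cols), grid,
                   reference_wavelength)
}
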