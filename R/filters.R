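gaussian_transfer <- function(rows, cols, sigma) {
  fy <- fft_freq(rows, 1)   # cycles per pixel; sigma is in pixels
  fx <- fft_freq(cols, 1)
  exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
}

apply_transfer <- function(x, G) {
  y <- stats::fft(stats::fft(x) * G, inverse = TRUE) / length(x)
  if (is.complex(x)) y else Re(y)
}

#' Gaussian low-pass and high-pass filters (frequency domain)
#'
#' Multiplies the 2-D spectrum by `G(f) = exp(-2 pi^2 sigma^2 |f|^2)` with
#' `f` in cycles per pixel, i.e. the transfer function of a Gaussian kernel
#' of standard deviation `sigma` pixels, with periodic boundary. The
#' high-pass is the exact complement `x - gaussian_lowpass(x, sigma)`, so
#' `lowpass + highpass == x` to double precision. Complex inputs (including
#' [complex_field()] objects) are filtered componentwise.
#'
#' @param x Numeric or complex matrix, or a [complex_field()].
#' @param sigma Gaussian kernel standard deviation in pixels, > 0.
#' @return Same type as `x`.
#' @export
gaussian_lowpass <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("gaussian_lowpass: sigma must be > 0", call. = FALSE)
  if (is_complex_field(x)) {
    G <- gaussian_transfer(x$grid$rows, x$grid$cols, sigma)
    out <- x
    out$values <- apply_transfer(x$values, G)
    return(out)
  }
  stopifnot(is.matrix(x))
  apply_transfer(x, gaussian_transfer(nrow(x), ncol(x), sigma))
}

#' @rdname gaussian_lowpass
#' @export
gaussian_highpass <- function(x, sigma) {
  lp <- gaussian_lowpass(x, sigma)
  if (is_complex_field(x)) {
    out <- x
    out$values <- x$values - lp$values
    return(out)
  }
  x - lp
}
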