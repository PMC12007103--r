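# Independent oracles used to validate the FFT-based implementations.

# Direct Rayleigh-Sommerfeld (first solution) point-by-point summation:
# U(p) = sum_q U0(q) * h(p - q), h(r) = z e^{ikr} / (2 pi r^2) (1/r - ik) dA.
# Quadratic cost; exact for the sampled-point-source model of the input.
rs_propagate_oracle <- function(u0, pitch, wavelength, z) {
  n <- nrow(u0)
  k <- 2 * pi / wavelength
  d <- ((-(n - 1)):(n - 1)) * pitch
  r <- sqrt(outer(d^2, d^2, `+`) + z^2)
  h <- z * exp(1i * k * r) / (2 * pi * r^2) * (1 / r - 1i * k) * pitch^2
  out <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (u0[i, j] != 0)
      out <- out + u0[i, j] * h[(n - i + 1):(2 * n - i), (n - j + 1):(2 * n - j)]
  }
  out
}

# Direct per-window SSIM: explicit loop over every complete 11x11 window
# with a Gaussian weight (std 1.5), K1 = 0.01, K2 = 0.03.
ssim_oracle <- function(x, y, L) {
  w1 <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- outer(w1, w1)
  w <- w / sum(w)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  nr <- nrow(x) - 10L
  nc <- ncol(x) - 10L
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    xa <- x[i:(i + 10), j:(j + 10)]
    ya <- y[i:(i + 10), j:(j + 10)]
    mu1 <- sum(w * xa); mu2 <- sum(w * ya)
    s11 <- sum(w * xa^2) - mu1^2
    s22 <- sum(w * ya^2) - mu2^2
    s12 <- sum(w * xa * ya) - mu1 * mu2
    vals[i, j] <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
      ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  }
  mean(vals)
}

# A band-limited random complex field (white noise pushed through a Gaussian
# low-pass) for unitarity/linearity properties.
random_bandlimited <- function(n, sigma = 2, seed = 1) {
  set.seed(seed)
  gaussian_lowpass(matrix(rnorm(n^2), n), sigma) +
    1i * gaussian_lowpass(matrix(rnorm(n^2), n), sigma)
}
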