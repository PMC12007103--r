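make_test_stack <- function(n = 128, text = "Q", distances = c(2e-3, 4e-3),
                            noise = noise_spec("none"), ...) {
  g <- grid_spec(n, n, 2e-6)
  obj <- make_text_phase_object(text, g, ...)
  list(obj = obj,
       stack = record_stack(obj, distances = distances, noise = noise))
}

test_that("hologram normalization has the stated closed forms", {
  g <- grid_spec(16, 16, 1e-6)
  hu <- hologram(matrix(3.7, 16, 16), 1e-3, 500e-9, g)
  expect_true(all(normalize_hologram(hu, "sqrt") == 1))
  expect_true(all(normalize_hologram(hu, "identity") == 1))
  two <- matrix(rep(c(1, 4), each = 128), 16)     # half 1, half 4, mean 2.5
  h2 <- hologram(two, 1e-3, 500e-9, g)
  a <- normalize_hologram(h2, "sqrt")
  expect_equal(sort(unique(as.vector(a))), sqrt(c(0.4, 1.6)), tolerance = 1e-12)
  expect_equal(mean(a^2), 1, tolerance = 1e-12)
  expect_equal(mean(normalize_hologram(h2, "identity")), 1, tolerance = 1e-12)
  expect_error(hologram(matrix(0, 16, 16), 1e-3, 500e-9, g) |>
                 normalize_hologram(), "zero mean")
})

test_that("GHR backpropagation: flat for empty scenes, twin image otherwise", {
  g <- grid_spec(64, 64, 2e-6)
  empty <- make_text_phase_object("Q", g, 0, 0)
  he <- record_hologram(empty, 3e-3)
  u <- reconstruct_ghr(he)
  expect_lt(sd(field_phase(u)), 1e-6)
  # amplitude object: the twin image leaves a nonzero residual
  amp <- make_amplitude_object("X", g)
  ha <- record_hologram(amp, 1e-3)
  ua <- reconstruct_ghr(ha)
  truth_n <- amp$amplitude / sqrt(mean(amp$amplitude^2))
  expect_gt(rms_error(field_amplitude(ua), truth_n), 1e-3)
  # deterministic
  expect_identical(reconstruct_ghr(ha)$values, ua$values)
})

test_that("a single-frame GS cycle reduces exactly to GHR", {
  ts <- make_test_stack(64, distances = 2e-3)
  one <- ts$stack
  u_gs <- reconstruct_gs(one, reconstruction_settings("gs", iterations = 1))
  u_ghr <- reconstruct_ghr(one$frames[[1]])
  expect_lt(max(Mod(u_gs$values - u_ghr$values)), 1e-10)
})

test_that("GS converges on clean data and diverges on noisy data", {
  ts <- make_test_stack(128, "GS")
  truth <- ts$obj$phase
  tr <- attr(reconstruct_gs(ts$stack,
                            reconstruction_settings("gs", iterations = 30),
                            trace_truth = truth, trace_what = "phase"),
             "rms_trace")
  expect_lt(tr[30], tr[1])
  noisy <- make_test_stack(128, "GS",
                           noise = noise_spec("gaussian", 0.05, seed = 21))
  trn <- attr(reconstruct_gs(noisy$stack,
                             reconstruction_settings("gs", iterations = 60),
                             trace_truth = truth, trace_what = "phase"),
              "rms_trace")
  expect_gt(trn[60], trn[1])
  # GS needs phase diversity in distance mode
  same_z <- record_stack(ts$obj, distances = c(2e-3, 2e-3))
  expect_error(reconstruct_gs(same_z), "distinct planes")
})

test_that("GA of one frame (or identical frames) is GHR; averaging is linear", {
  ts <- make_test_stack(64, distances = 3e-3)
  u_ga <- reconstruct_ga(ts$stack)
  u_ghr <- reconstruct_ghr(ts$stack$frames[[1]])
  expect_lt(max(Mod(u_ga$values - u_ghr$values)), 1e-12)
  rep3 <- hologram_stack(rep(ts$stack$frames, 3), "distance")
  expect_lt(max(Mod(reconstruct_ga(rep3)$values - u_ghr$values)), 1e-12)
})

test_that("Gaussian low/high-pass are an exact complementary pair", {
  set.seed(9)
  x <- matrix(rnorm(64^2), 64)
  lp <- gaussian_lowpass(x, 2)
  hp <- gaussian_highpass(x, 2)
  expect_lt(max(abs(lp + hp - x)), 1e-14)
  expect_lt(abs(mean(hp)), 1e-12)
  # DC preservation and the delta-kernel limit
  cst <- matrix(4.2, 32, 32)
  expect_lt(max(abs(gaussian_lowpass(cst, 3) - 4.2)), 1e-12)
  expect_lt(max(abs(gaussian_highpass(cst, 3))), 1e-12)
  expect_lt(max(abs(gaussian_lowpass(x, 1e-6) - x)), 1e-9)
  expect_error(gaussian_lowpass(x, 0), "sigma")
})

test_that("low-pass attenuates Nyquist by the closed-form transfer value", {
  set.seed(3)
  n <- 64
  x <- matrix(rnorm(n^2), n)
  y <- gaussian_lowpass(x, 2)
  X <- stats::fft(x); Y <- stats::fft(y)
  # Nyquist bin along each axis sits at index n/2 + 1 (frequency 1/2 cyc/px);
  # G there is ~1e-9, at the FFT noise floor, so compare absolutely
  gq <- exp(-2 * pi^2 * 2^2 * 0.25)
  expect_lt(abs(Mod(Y[n / 2 + 1, 1]) / Mod(X[n / 2 + 1, 1]) - gq), 1e-12)
  # mid-band bin (1/4 cyc/px) is far above the noise floor: relative check
  gm <- exp(-2 * pi^2 * 2^2 * (1 / 16))
  expect_equal(Mod(Y[n / 4 + 1, 1]) / Mod(X[n / 4 + 1, 1]), gm, tolerance = 1e-9)
})

test_that("IGA collapses to GS as sigma approaches zero", {
  ts <- make_test_stack(64, noise = noise_spec("poisson", 0.05, seed = 13))
  u_gs <- reconstruct_gs(ts$stack, reconstruction_settings("gs", iterations = 10))
  u_iga <- reconstruct_iga(ts$stack,
                           reconstruction_settings("iga", iterations = 10,
                                                   sigma = 1e-6))
  expect_lt(sqrt(mean(Mod(u_gs$values - u_iga$values)^2)), 1e-6)
  expect_error(reconstruct_iga(hologram_stack(ts$stack$frames[1], "distance"),
                               reconstruction_settings("iga", iterations = 2)),
               "2 frames")
})

test_that("IGA fuses the GS band below sigma with the GA band above it", {
  ts <- make_test_stack(128, "QPI",
                        noise = noise_spec("poisson", 0.15, seed = 8))
  truth <- ts$obj$phase
  err <- function(u) rms_error(field_phase(u), truth, piston = TRUE)
  e_gs <- err(reconstruct_gs(ts$stack, reconstruction_settings("gs", iterations = 30)))
  e_ga <- err(reconstruct_ga(ts$stack))
  e_iga <- err(reconstruct_iga(ts$stack,
                               reconstruction_settings("iga", iterations = 30)))
  expect_lt(e_iga, e_gs)            # strong noise: the GS path alone is worse
  expect_lt(e_iga, 1.2 * e_ga)
})

test_that("phase rescaling between wavelengths preserves the OPD", {
  g <- grid_spec(32, 32, 2e-6)
  set.seed(5)
  ph <- matrix(runif(32^2, -0.5, 0.5), 32)
  u <- complex_field(exp(1i * ph), g, 450e-9, "object")
  r <- rescale_phase_wavelength(u, 635e-9)
  expect_equal(field_phase(r), ph * 450 / 635, tolerance = 1e-12)
  expect_equal(r$wavelength, 635e-9)
  expect_equal(field_amplitude(r), field_amplitude(u), tolerance = 1e-12)
  # identity and involution
  expect_equal(rescale_phase_wavelength(u, 450e-9)$values, u$values,
               tolerance = 1e-12)
  back <- rescale_phase_wavelength(r, 450e-9)
  expect_lt(max(Mod(back$values - u$values)), 1e-12)
  expect_error(rescale_phase_wavelength(u, -1), "target_wavelength")
  # worked number: 0.1 rad at 450 nm reads 0.0708... rad at 635 nm
  u1 <- complex_field(matrix(exp(1i * 0.1), 32, 32), g, 450e-9)
  expect_equal(field_phase(rescale_phase_wavelength(u1, 635e-9))[1, 1],
               0.1 * 450 / 635, tolerance = 1e-12)
})

test_that("wavelength-multiplexed GS beats single-frame GHR", {
  g <- grid_spec(128, 128, 2e-6)
  obj <- make_text_phase_object("Q", g, reference_wavelength = 450e-9)
  st <- record_stack(obj, distances = 3e-3,
                     wavelengths = c(450e-9, 532e-9, 635e-9))
  truth <- obj$phase
  e_ghr <- rms_error(field_phase(reconstruct_ghr(st$frames[[1]])), truth,
                     piston = TRUE)
  u_gs <- reconstruct_gs(st, reconstruction_settings("gs", iterations = 30))
  e_gs <- rms_error(field_phase(u_gs), truth, piston = TRUE)
  expect_lt(e_gs, e_ghr)
  expect_equal(u_gs$wavelength, 450e-9)   # output at the first wavelength
  # all reconstructors are deterministic
  u2 <- reconstruct_gs(st, reconstruction_settings("gs", iterations = 30))
  expect_identical(u_gs$values, u2$values)
})

test_that("the reconstruct() front-end dispatches on the settings", {
  ts <- make_test_stack(64)
  for (m in c("ghr", "gs", "ga", "iga")) {
    u <- reconstruct(ts$stack, reconstruction_settings(m, iterations = 3))
    expect_s3_class(u, "complex_field")
    expect_identical(u$plane_tag, "object")
  }
  expect_error(reconstruction_settings("iga", sigma = 0), "sigma")
  expect_error(reconstruction_settings("gs", iterations = 0), "iterations")
})
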