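test_that("text phase objects honour the requested phase range exactly", {
  g <- grid_spec(128, 128, 2e-6)
  obj <- make_text_phase_object("QPI", g)         # defaults -0.4 .. 0.6 rad
  expect_equal(min(obj$phase), -0.4)
  expect_equal(max(obj$phase), 0.6)
  expect_true(all(obj$phase >= -0.4 & obj$phase <= 0.6))
  expect_true(all(obj$amplitude == 1))
  # degenerate range = empty object
  e <- make_text_phase_object("Q", g, 0, 0)
  expect_true(all(e$phase == 0))
  # deterministic, byte-identical rendering
  expect_identical(make_text_phase_object("QPI", g)$phase, obj$phase)
  # glyphs larger than the grid
  expect_error(make_text_phase_object("WWWWWWWW", grid_spec(8, 8, 1e-6), scale = 2),
               "larger than grid")
})

test_that("amplitude objects are absorbing features on a bright background", {
  g <- grid_spec(64, 64, 2e-6)
  obj <- make_amplitude_object("X", g)            # defaults 0 .. 1
  expect_true(all(obj$amplitude >= 0 & obj$amplitude <= 1))
  expect_equal(max(obj$amplitude), 1)             # background transmits
  expect_true(all(obj$phase == 0))
  e <- make_amplitude_object("X", g, amp_min = 1, amp_max = 1)
  expect_true(all(e$amplitude == 1))
})

test_that("optical path difference view is wavelength-independent", {
  g <- grid_spec(64, 64, 2e-6)
  o1 <- make_text_phase_object("Q", g, reference_wavelength = 500e-9)
  opd <- object_opd(o1)
  # same OPD stated at another wavelength: phase scales, OPD does not
  o2 <- synthetic_object(o1$phase * 500 / 635, o1$amplitude, g,
                         reference_wavelength = 635e-9)
  expect_equal(object_opd(o2), opd, tolerance = 1e-12)
})

test_that("resolution target uses the closed-form bar width rule", {
  expect_identical(resolution_bar_width(8, 1), 8L)
  expect_identical(resolution_bar_width(8, 7), 4L)      # halves every 6 elements
  for (e in 1:6)
    expect_identical(resolution_bar_width(12, e),
                     max(1L, as.integer(round(12 * 2^(-(e - 1) / 6)))))
  g <- grid_spec(128, 128, 2.4e-6)
  tgt <- make_resolution_target(g, step_phase = 8.47e-2, base_width_px = 6)
  expect_equal(max(tgt$phase), 8.47e-2)
  expect_equal(min(tgt$phase), 0)
  empty <- make_resolution_target(g, step_phase = 0, base_width_px = 6)
  expect_true(all(empty$phase == 0))
  expect_true(all(tgt$amplitude == 1))
})

test_that("an empty object records a perfectly uniform hologram", {
  g <- grid_spec(64, 64, 2e-6)
  e <- make_text_phase_object("Q", g, 0, 0)
  h <- record_hologram(e, 3e-3)
  expect_lt(max(abs(h$intensity - 1)), 1e-10)
})

test_that("pure phase objects conserve energy: hologram mean stays 1", {
  g <- grid_spec(128, 128, 2e-6)
  obj <- make_text_phase_object("QPI", g)
  for (z in c(2e-3, 4e-3)) {
    h <- record_hologram(obj, z)
    expect_equal(mean(h$intensity), 1, tolerance = 1e-3)
  }
  # and the recording is deterministic without noise
  expect_identical(record_hologram(obj, 2e-3)$intensity,
                   record_hologram(obj, 2e-3)$intensity)
})

test_that("shot noise matches its target standard deviation at unit mean", {
  i1 <- matrix(1, 1000, 1000)
  expect_identical(add_shot_noise(i1, noise_spec("none")), i1)
  expect_identical(add_shot_noise(i1, noise_spec("poisson", 0, seed = 1)), i1)
  g <- add_shot_noise(i1, noise_spec("gaussian", 0.05, seed = 7))
  expect_equal(sd(g - i1), 0.05, tolerance = 0.01)        # within 1%
  for (s in c(0.05, 0.1, 0.2)) {
    p <- add_shot_noise(i1, noise_spec("poisson", s, seed = 11))
    expect_equal(sd(p), s, tolerance = 0.01)              # within 1%
    expect_equal(mean(p), 1, tolerance = 5 * s / 1000)   # unbiased
  }
  expect_error(noise_spec("none", 0.1), "meaningless")
})

test_that("noise draws are reproducible from the seed", {
  i1 <- matrix(1, 50, 50)
  a <- add_shot_noise(i1, noise_spec("poisson", 0.1, seed = 3))
  b <- add_shot_noise(i1, noise_spec("poisson", 0.1, seed = 3))
  d <- add_shot_noise(i1, noise_spec("poisson", 0.1, seed = 4))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("quantization clips, rounds, and is idempotent at unit gain", {
  i <- matrix(c(0.2, 0.7, 1.4, 300), 2)
  cam8 <- camera_model(bit_depth = 8)
  dn <- quantize(i, cam8)
  expect_identical(dn, matrix(c(0, 1, 1, 255), 2))
  # saturation
  expect_true(all(quantize(i, camera_model(8, gain = 1e6)) == 255))
  # few first gray levels under a tiny exposure
  lows <- quantize(matrix(runif(100, 0.9, 1.1), 10),
                   camera_model(8, exposure_scale = 1e-2))
  expect_true(all(lows %in% c(0, 1)))
  # idempotent on integer input at unit scaling
  expect_identical(quantize(dn, cam8), dn)
})

test_that("record_stack builds consistent multiplexed stacks reproducibly", {
  g <- grid_spec(64, 64, 2e-6)
  obj <- make_text_phase_object("Q", g)
  st <- record_stack(obj, distances = c(2e-3, 3e-3, 4e-3),
                     noise = noise_spec("poisson", 0.1, seed = 5))
  expect_s3_class(st, "hologram_stack")
  expect_length(st$frames, 3)
  expect_identical(st$multiplex_mode, "distance")
  # same seed -> identical stack; frames are independent draws
  st2 <- record_stack(obj, distances = c(2e-3, 3e-3, 4e-3),
                      noise = noise_spec("poisson", 0.1, seed = 5))
  expect_identical(lapply(st$frames, `[[`, "intensity"),
                   lapply(st2$frames, `[[`, "intensity"))
  expect_false(identical(st$frames[[1]]$intensity, st$frames[[2]]$intensity))
  # single frame stack degenerates gracefully
  one <- record_stack(obj, distances = 2e-3)
  expect_length(one$frames, 1)
  # wavelength mode
  wl <- record_stack(obj, distances = 3e-3,
                     wavelengths = c(450e-9, 532e-9, 635e-9))
  expect_identical(wl$multiplex_mode, "wavelength")
  # inconsistent stacks are rejected
  h1 <- record_hologram(obj, 2e-3, 500e-9)
  h2 <- record_hologram(obj, 3e-3, 635e-9)
  expect_error(hologram_stack(list(h1, h2), "distance"), "single wavelength")
  expect_error(hologram_stack(list(h1, h2), "wavelength"), "single distance")
})
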