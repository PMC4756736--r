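test_that("phantom rendering matches the specified geometry", {
  # uniform water field
  w <- make_phantom(phantom_spec("water", background_hu = 0))
  expect_true(all(w$pixels == 0))

  # low-contrast disk: centre at background + contrast, far field at background
  sp <- phantom_spec("catphan_lowcontrast", background_hu = 63.4,
                     disk_contrast_hu = 10, disk_diameter_mm = 10)
  img <- make_phantom(sp)
  co <- pixel_coords(img)
  i <- which.min(abs(co$y)); j <- which.min(abs(co$x))
  expect_equal(img$pixels[i, j], 73.4)
  expect_equal(img$pixels[4, 4], 63.4)
  # anti-aliased rim: coverage strictly between background and disk level
  rim <- abs(sqrt(outer(co$y^2, co$x^2, `+`)) - 5) < 0.5
  expect_true(any(img$pixels[rim] > 63.4 & img$pixels[rim] < 73.4))

  # wire: peak within half a pixel of the requested offset, fixed line integral
  ws <- phantom_spec("wire", wire_offset_mm = c(5, 5))
  wi <- make_phantom(ws)
  k <- which(wi$pixels == max(wi$pixels), arr.ind = TRUE)[1, ]
  cw <- pixel_coords(wi)
  expect_lt(abs(cw$x[k[2]] - 5), wi$spacing_mm[2] / 2 + 1e-9)
  expect_lt(abs(cw$y[k[1]] - 5), wi$spacing_mm[1] / 2 + 1e-9)
  expect_equal(sum(wi$pixels) * prod(wi$spacing_mm), ws$wire_hu_mm2)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec("catphan_lowcontrast", disk_diameter_mm = 0),
               "disk_diameter_mm")
  expect_error(phantom_spec("catphan_lowcontrast", disk_diameter_mm = 300),
               "field of view")
  expect_error(phantom_spec("nonsense"))
  expect_error(phantom_spec("wire", wire_offset_mm = c(30, 0)), "offset")
})

test_that("noise calibration maps targets to the reference sigma", {
  sp <- phantom_spec("catphan_lowcontrast", disk_contrast_hu = 10)
  acq <- acquisition_params()
  expect_equal(calibrate_noise("cnr", 1.18, sp, acq), 10 / 1.18)
  expect_equal(calibrate_noise("mse_plateau", 151.0, sp, acq), sqrt(151 / 2))
  expect_equal(calibrate_noise("sd", 1, sp, acq), 1)
  # IR flavor: reference sigma is inflated so the IR-scaled noise hits target
  ir <- acquisition_params(recon_flavor = "IR_like", ir_noise_scale = 0.8)
  expect_equal(calibrate_noise("sd", 4, sp, ir) * 0.8, 4)
  expect_error(calibrate_noise("cnr", -1, sp, acq), "positive")
})

test_that("simulated noise follows the triangular window correlation law", {
  sp <- phantom_spec("water", grid_size = 320)
  acq <- acquisition_params(sigma_ref_hu = 8, window_ms = 70)
  for (iv in c(10, 30, 50, 70, 90)) {
    ser <- simulate_series(sp, acq, n_phases = 2, interval_ms = iv,
                           seed = 300 + iv)
    n1 <- frame_noise(ser, 1); n2 <- frame_noise(ser, 2)
    expect_lt(abs(stats::cor(c(n1), c(n2)) - max(0, 1 - iv / 70)), 0.02)
  }
})

test_that("noise is unbiased and SD scales as 1/sqrt(dose)", {
  sp <- phantom_spec("water", grid_size = 256)
  base <- acquisition_params(mas_per_rot = 456, sigma_ref_hu = 8)
  quarter <- acquisition_params(mas_per_rot = 114, sigma_ref_hu = 8)
  s1 <- simulate_series(sp, base, 1, 50, seed = 11)
  s2 <- simulate_series(sp, quarter, 1, 50, seed = 12)
  n1 <- frame_noise(s1, 1); n2 <- frame_noise(s2, 1)
  expect_lt(abs(mean(n1)), 0.05)
  expect_lt(abs(stats::sd(c(n2)) / stats::sd(c(n1)) - 2), 0.04)
  expect_equal(noise_sigma(quarter) / noise_sigma(base), 2)
  # IR-like flavor scales noise down
  ir <- acquisition_params(sigma_ref_hu = 8, recon_flavor = "IR_like",
                           ir_noise_scale = 0.5)
  s3 <- simulate_series(sp, ir, 1, 50, seed = 13)
  expect_lt(abs(stats::sd(c(frame_noise(s3, 1))) - 4), 0.1)
})

test_that("colored noise is rescaled back to the target SD", {
  sp <- phantom_spec("water", grid_size = 256)
  acq <- acquisition_params(sigma_ref_hu = 8, noise_colored = TRUE)
  ser <- simulate_series(sp, acq, 1, 50, seed = 21)
  expect_lt(abs(stats::sd(c(frame_noise(ser, 1))) / 8 - 1), 0.05)
})

test_that("series simulation is deterministic under a fixed seed", {
  sp <- tiny_water()
  acq <- acquisition_params(sigma_ref_hu = 5)
  a <- simulate_series(sp, acq, 3, 50, seed = 7)
  b <- simulate_series(sp, acq, 3, 50, seed = 7)
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
  # sigma = 0 reduces every frame to the blurred ground truth
  z <- simulate_series(sp, acquisition_params(sigma_ref_hu = 0), 3, 50,
                       seed = 7)
  expect_equal(z$frames[[1]]$pixels,
               gaussian_blur(z$ground_truth$pixels, 0.62,
                             z$ground_truth$spacing_mm))
  expect_identical(z$frames[[1]]$pixels, z$frames[[3]]$pixels)
})

test_that("incommensurate interval and window are rejected", {
  expect_error(simulate_series(tiny_water(), acquisition_params(window_ms = 70),
                               3, interval_ms = 50.003, seed = 1),
               "0.1 ms")
  expect_error(simulate_series(tiny_water(), acquisition_params(), 0, 50),
               "n_phases")
})
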