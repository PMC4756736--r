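test_that("registration recovers constructed shifts and applies them", {
  img <- make_phantom(tiny_catphan(64))
  set.seed(4)
  img$pixels <- img$pixels + matrix(stats::rnorm(64^2, 0, 5), 64, 64)

  d0 <- register_pair(img, img, "identity")
  expect_identical(d0$shift_px, c(0L, 0L))

  # moving = fixed displaced by (3 rows, 0 cols)
  sh <- img
  sh$pixels <- rbind(img$pixels[62:64, ], img$pixels[1:61, ])
  d <- register_pair(sh, img, "translation")
  expect_identical(d$shift_px, c(3L, 0L))
  back <- apply_displacement(sh, d)
  expect_equal(back$pixels[10:50, 10:50], img$pixels[10:50, 10:50])

  # static phantom frames (high-contrast structure, independent noise):
  # no motion to recover
  ser <- simulate_series(phantom_spec("wire", grid_size = 128),
                         acquisition_params(sigma_ref_hu = 8,
                                            window_ms = 10),
                         3, 90, seed = 9)
  ds <- register_pair(ser$frames[[1]], ser$frames[[2]], "translation")
  expect_identical(ds$shift_px, c(0L, 0L))

  expect_error(register_pair(img, phase_image(matrix(0, 8, 8), 1)), "shape")
})

test_that("phase interpolation blends images and noise correctly", {
  ser <- iid_series(sigma = 8, grid = 128, seed = 14)
  a <- ser$frames[[1]]; b <- ser$frames[[2]]
  expect_identical(interpolate_phase(a, b, 0)$pixels, a$pixels)
  expect_error(interpolate_phase(a, b, 1.2), "alpha")

  # constant images: mean preservation
  ca <- phase_image(matrix(63.4, 16, 16), 1, 0)
  cb <- phase_image(matrix(63.4, 16, 16), 1, 50)
  half <- interpolate_phase(ca, cb, 0.5)
  expect_true(all(half$pixels == 63.4))
  expect_equal(half$phase_ms, 25)

  # midpoint of two iid fields has SD sigma / sqrt(2)
  gtb <- gaussian_blur(ser$ground_truth$pixels, 0.62,
                       ser$ground_truth$spacing_mm)
  mid <- interpolate_phase(a, b, 0.5)
  sd_in <- stats::sd(c(a$pixels - gtb))
  sd_out <- stats::sd(c(mid$pixels - gtb))
  expect_lt(abs(sd_out / (sd_in / sqrt(2)) - 1), 0.02)
})

test_that("temporal filtering weights, renormalizes and preserves the mean", {
  ser <- iid_series(sigma = 8, grid = 128, seed = 2)
  gtb <- gaussian_blur(ser$ground_truth$pixels, 0.62,
                       ser$ground_truth$spacing_mm)
  sigma <- stats::sd(c(ser$frames[[2]]$pixels - gtb))

  # single frame: degenerate renormalized case
  one <- phase_series(ser$frames[2], ser$interval_ms)
  expect_identical(temporal_filter(one)$pixels, ser$frames[[2]]$pixels)

  # identical frames: filter is the identity
  same <- phase_series(lapply(c(-50, 0, 50), function(t)
    phase_image(ser$frames[[2]]$pixels, ser$frames[[2]]$spacing_mm, t)), 50)
  expect_equal(temporal_filter(same)$pixels, ser$frames[[2]]$pixels)

  # weighted-variance law on iid frames: w = 0.3 -> sd factor 0.583
  out <- temporal_filter(ser, legato_params(neighbor_weight = 0.3))
  expect_lt(abs(stats::sd(c(out$pixels - gtb)) /
                  (sigma * sqrt(0.4^2 + 2 * 0.3^2)) - 1), 0.03)
  # equal weights w = 1/3 -> sd factor 1/sqrt(3)
  out3 <- temporal_filter(ser, legato_params(neighbor_weight = 1 / 3))
  expect_lt(abs(stats::sd(c(out3$pixels - gtb)) / (sigma / sqrt(3)) - 1), 0.03)

  # mean attenuation preserved across 10 replicate study-scale series
  dev <- vapply(1:10, function(r) {
    s <- iid_series(sigma = 8, grid = 256, seed = 100 + r)
    mean(legato(s)$pixels) - mean(s$frames[[2]]$pixels)
  }, numeric(1))
  expect_lt(max(abs(dev)), 0.1)

  expect_error(temporal_filter(phase_series(ser$frames[1:2], 90)), "center")
  expect_error(legato_params(neighbor_weight = 0.7), "neighbor_weight")
})

test_that("legato pipeline reduces noise per the correlation quadratic form", {
  # noiseless series: output equals the (blurred) ground truth exactly
  z <- simulate_series(tiny_water(), acquisition_params(sigma_ref_hu = 0),
                       3, 50, seed = 1)
  expect_identical(legato(z)$pixels, z$frames[[2]]$pixels)
  expect_equal(legato(z)$phase_ms, 0)

  # correlated frames at 10 ms lag (rho = 6/7, 5/7): Monte-Carlo SD vs the
  # quadratic form w' Sigma w = 0.34 + 0.48 * 6/7 + 0.18 * 5/7
  sp <- phantom_spec("water", grid_size = 256)
  acq <- acquisition_params(sigma_ref_hu = 8, window_ms = 70)
  pred <- 8 * sqrt(0.34 + 0.48 * 6 / 7 + 0.18 * 5 / 7)
  sds <- vapply(1:5, function(r) {
    ser <- simulate_series(sp, acq, 3, 10, seed = 40 + r)
    gtb <- gaussian_blur(ser$ground_truth$pixels, 0.62,
                         ser$ground_truth$spacing_mm)
    stats::sd(c(legato(ser)$pixels - gtb))
  }, numeric(1))
  expect_lt(abs(mean(sds) / pred - 1), 0.03)
})

test_that("averaging cannot beat the independent-information bound", {
  # with any 3-frame weights (and linear interpolants included), output SD
  # of iid frames is >= sigma / sqrt(3)
  ser <- iid_series(sigma = 8, grid = 128, seed = 33)
  gtb <- gaussian_blur(ser$ground_truth$pixels, 0.62,
                       ser$ground_truth$spacing_mm)
  bound <- stats::sd(c(ser$frames[[2]]$pixels - gtb)) / sqrt(3)
  for (w in c(0.1, 0.25, 1 / 3, 0.45)) {
    for (inc in c(FALSE, TRUE)) {
      out <- legato(ser, legato_params(neighbor_weight = w, interp_factor = 1,
                                       include_interpolated = inc))
      expect_gt(stats::sd(c(out$pixels - gtb)), bound * 0.99)
    }
  }
})

test_that("filtered CNR is non-decreasing in interval up to the window", {
  sp <- phantom_spec("catphan_lowcontrast", grid_size = 128)
  acq <- acquisition_params(sigma_ref_hu = 10 / 1.18, window_ms = 70)
  tg <- roi_spec(c(0, 0), 4, "target")
  bg <- roi_spec(c(25, 0), 10, "background")
  mean_cnr <- vapply(c(10, 40, 70, 90), function(iv) {
    mean(vapply(1:8, function(r) {
      ser <- simulate_series(sp, acq, 3, iv, seed = 600 + 10 * iv + r)
      cnr(legato(ser), tg, bg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cnr[1:3]) > 0))
  # flat beyond the window within Monte-Carlo tolerance
  expect_lt(abs(mean_cnr[4] - mean_cnr[3]), 0.25)
})
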