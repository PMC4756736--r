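test_that("CNR arithmetic, errors and scale equivariance", {
  # calibrated noise field: CNR approaches contrast / sigma in expectation
  sp <- phantom_spec("catphan_lowcontrast", grid_size = 256)
  acq <- acquisition_params(sigma_ref_hu = 10 / 1.18)
  tg <- roi_spec(c(0, 0), 4, "target")
  bg <- roi_spec(c(25, 0), 10, "background")
  vals <- vapply(1:12, function(r) {
    ser <- simulate_series(sp, acq, 1, 50, seed = 700 + r)
    cnr(ser$frames[[1]], tg, bg)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1.18), 3 * stats::sd(vals) / sqrt(12) + 0.02)

  # scaling the noise by c scales CNR by 1/c in expectation: with paired
  # realizations, mean(c * CNR_scaled - CNR) vanishes up to the ROI-mean
  # noise term
  dev <- vapply(1:12, function(r) {
    ser <- simulate_series(sp, acq, 1, 50, seed = 700 + r)
    img <- ser$frames[[1]]
    gtb <- gaussian_blur(ser$ground_truth$pixels, 0.62,
                         ser$ground_truth$spacing_mm)
    img2 <- phase_image(gtb + 2 * (img$pixels - gtb), img$spacing_mm)
    2 * cnr(img2, tg, bg) - cnr(img, tg, bg)
  }, numeric(1))
  expect_lt(abs(mean(dev)), 0.1)

  # equal-statistics ROIs give CNR 0
  flat <- phase_image(matrix(rep(c(62, 64), 128), 16, 16), 1)
  expect_equal(cnr(flat, roi_spec(c(-4, 0), 2), roi_spec(c(4, 0), 2)), 0)

  const <- phase_image(matrix(5, 16, 16), 1)
  expect_error(cnr(const, roi_spec(c(-4, 0), 2), roi_spec(c(4, 0), 2)),
               "SD is zero")
  expect_error(cnr(flat, roi_spec(c(0, 0), 3), roi_spec(c(1, 0), 3)),
               "disjoint")
  expect_error(roi_mask(flat, roi_spec(c(7, 0), 3)), "outside")
})

test_that("MSE is the mean squared pixel difference with its symmetries", {
  a <- phase_image(matrix(0, 2, 2), 1)
  b <- phase_image(matrix(c(1, 1, 3, 1), 2, 2), 1)
  expect_equal(mse(a, b), 3)
  expect_equal(mse(a, b), mse(b, a))
  expect_equal(mse(a, a), 0)
  expect_error(mse(a, phase_image(matrix(0, 3, 3), 1)), "shape")

  # two independent frames at sigma = sqrt(151/2): E[MSE] = 151
  sp <- phantom_spec("water", grid_size = 256)
  acq <- acquisition_params(sigma_ref_hu = sqrt(151 / 2), window_ms = 10)
  m <- vapply(1:6, function(r) {
    ser <- simulate_series(sp, acq, 2, 90, seed = 800 + r)
    mse(ser$frames[[1]], ser$frames[[2]])
  }, numeric(1))
  expect_lt(abs(mean(m) / 151 - 1), 0.02)
})

test_that("ROI noise SD uses the sample convention", {
  two <- matrix(0, 4, 4)
  two[2, 2] <- 62; two[3, 2] <- 64   # pixel centres (x = -0.5, y = -/+0.5)
  expect_equal(noise_sd(phase_image(two, 1),
                        roi_spec(c(-0.5, 0), 0.6)), sqrt(2))
  expect_equal(noise_sd(phase_image(matrix(7, 16, 16), 1),
                        roi_spec(c(0, 0), 5)), 0)
  # calibrated field: SD recovered within sampling error on a ~1e4 px ROI
  sp <- phantom_spec("water", grid_size = 128, field_of_view_mm = 128)
  ser <- simulate_series(sp, acquisition_params(sigma_ref_hu = 8.475),
                         1, 50, seed = 5)
  expect_lt(abs(noise_sd(ser$frames[[1]], roi_spec(c(0, 0), 55)) - 8.475),
            0.2)
})

test_that("wire-method MTF matches the Gaussian closed form", {
  # MTF(f) = exp(-2 pi^2 s^2 f^2) with s the total PSF width
  ws <- phantom_spec("wire")
  gt <- make_phantom(ws)
  sw <- ws$wire_fwhm_mm / (2 * sqrt(2 * log(2)))
  for (s in c(0.4, 0.6, 0.8)) {
    img <- phase_image(gaussian_blur(gt$pixels, s, gt$spacing_mm),
                       gt$spacing_mm)
    est <- mtf_wire(img, ws$wire_offset_mm)
    closed <- sqrt(log(10) / (2 * pi^2 * (s^2 + sw^2)))
    expect_lt(abs(est$mtf10 / closed - 1), 0.03)
    expect_equal(est$values[1], 1)
    expect_true(all(est$values >= 0))
  }
  # sub-pixel wire without blur: modulation stays at 1, MTF10 not reached
  thin <- make_phantom(phantom_spec("wire", wire_fwhm_mm = 0.02))
  m0 <- mtf_wire(thin, c(5, 5))
  expect_true(all(m0$values > 0.99))
  expect_true(is.na(m0$mtf10))
  # no wire above the noise floor
  ser <- simulate_series(phantom_spec("water", field_of_view_mm = 50,
                                      grid_size = 128),
                         acquisition_params(sigma_ref_hu = 8), 1, 50,
                         seed = 3)
  expect_error(mtf_wire(ser$frames[[1]]), "wire not found")
})

test_that("averaging registered noisy wire frames leaves MTF10 unchanged", {
  ks <- calibrate_kernel(0.55)
  expect_lt(abs(ks - sqrt(log(10) / (2 * pi^2 * 0.55^2))), 0.02)
  acq <- acquisition_params(sigma_ref_hu = 10 / 1.18, kernel_sigma_mm = ks,
                            window_ms = 50)
  d <- vapply(1:5, function(r) {
    ser <- simulate_series(phantom_spec("wire"), acq, 3, 50, seed = 900 + r)
    mtf_wire(legato(ser), c(5, 5))$mtf10 -
      mtf_wire(ser$frames[[2]], c(5, 5))$mtf10
  }, numeric(1))
  # mean shift stays within 0.01 cycles/mm; per-replicate scatter is
  # dominated by the noisier single-frame estimate
  expect_lt(abs(mean(d)), 0.01)
  expect_lt(max(abs(d)), 0.02)
})

test_that("NPS is flat for white noise and integrates to the variance", {
  px <- 0.5
  flds <- lapply(1:10, function(i) {
    set.seed(1000 + i)
    phase_image(matrix(stats::rnorm(128^2, 0, 8), 128, 128), px)
  })
  np <- nps_radial(flds, 64)
  expect_lt(abs(mean(np$values) / (64 * px^2) - 1), 0.05)   # 16 HU^2 mm^2
  expect_lt(abs(np$total_variance / 64 - 1), 0.05)          # Parseval
  expect_true(all(np$values >= 0))
  expect_lte(max(np$radial_frequencies), 1 / (2 * px))

  # Parseval also holds for kernel-colored noise
  sp <- phantom_spec("water", grid_size = 128)
  acq <- acquisition_params(sigma_ref_hu = 8, noise_colored = TRUE)
  imgs <- lapply(1:10, function(r)
    simulate_series(sp, acq, 1, 50, seed = 1100 + r)$frames[[1]])
  nf <- ensemble_noise_fields(imgs)
  npc <- nps_radial(nf, 64)
  v <- mean(vapply(nf, function(f) stats::var(c(f$pixels)), numeric(1)))
  expect_lt(abs(npc$total_variance / v - 1), 0.05)

  # zero noise: NPS identically zero
  z <- lapply(1:2, function(i) phase_image(matrix(0, 64, 64), px))
  expect_equal(max(nps_radial(z, 32)$values), 0)
  expect_error(nps_radial(z, 128), "larger")
})

test_that("equal-weight 3-frame averaging drops the NPS by 1/3 uniformly", {
  sp <- phantom_spec("water", grid_size = 128)
  acq <- acquisition_params(sigma_ref_hu = 8, window_ms = 10)
  refs <- legs <- list()
  for (r in 1:10) {
    ser <- simulate_series(sp, acq, 3, 90, seed = 1200 + r)
    refs[[r]] <- ser$frames[[2]]
    legs[[r]] <- legato(ser, legato_params(neighbor_weight = 1 / 3))
  }
  ratio <- nps_radial(ensemble_noise_fields(legs), 64)$values /
    nps_radial(ensemble_noise_fields(refs), 64)$values
  expect_lt(abs(mean(ratio) - 1 / 3), 0.03)
  expect_lt(stats::sd(ratio) / mean(ratio), 0.10)
})
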