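# Small shared fixtures: tiny grids keep the unit tests fast; the
# acceptance tests use the full 256-pixel study grids.

tiny_water <- function(grid = 64) phantom_spec("water", grid_size = grid)

tiny_catphan <- function(grid = 128)
  phantom_spec("catphan_lowcontrast", grid_size = grid)

# iid-noise series on a uniform phantom: interval beyond the window, so
# frames are independent
iid_series <- function(sigma = 8, n_phases = 3, grid = 64, seed = 1) {
  simulate_series(tiny_water(grid),
                  acquisition_params(sigma_ref_hu = sigma, window_ms = 10),
                  n_phases = n_phases, interval_ms = 90, seed = seed)
}

# noise residual of a frame relative to the blurred ground truth
frame_noise <- function(series, i, acq = NULL, kernel_sigma_mm = 0.62) {
  gt <- series$ground_truth
  b <- gaussian_blur(gt$pixels, kernel_sigma_mm, gt$spacing_mm)
  series$frames[[i]]$pixels - b
}

# numeric vector with exact mean and sd (n >= 2) for verdict-machinery tests
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
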