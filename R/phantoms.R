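#' Digital phantom specification
#'
#' Describes one of the three static phantoms the bench emulates:
#' a Catphan CTP515-like low-contrast slice (uniform background plus one
#' low-contrast disk), a thin-wire slice offset from isocenter for
#' wire-method MTF estimation, and a uniform water slice for NPS estimation.
#'
#' Field-of-view defaults follow the scan protocol the bench models:
#' 250 mm (Catphan), 50 mm (wire, so the wire point-spread function is
#' oversampled), 200 mm (water).
#'
#' @param kind one of `"catphan_lowcontrast"`, `"wire"`, `"water"`.
#' @param background_hu uniform background attenuation (HU). Defaults to
#'   63.4 HU for the Catphan slice (the measured module background this bench
#'   is calibrated to) and 0 HU otherwise.
#' @param disk_contrast_hu added attenuation of the low-contrast disk (HU).
#' @param disk_diameter_mm diameter of the low-contrast disk (mm).
#' @param wire_offset_mm length-2 offset (x, y) of the wire from the image
#'   centre, mm. Off-centre placement gives sub-pixel sampling phases for the
#'   oversampled PSF profile.
#' @param wire_fwhm_mm intrinsic full width at half maximum of the wire, mm.
#' @param wire_hu_mm2 line integral of the wire impulse (HU mm^2); the
#'   rendered wire is normalized so that sum(pixels) * pixel_area equals it.
#' @param field_of_view_mm reconstructed field of view, mm.
#' @param grid_size pixels per side of the square grid.
#' @return object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec("catphan_lowcontrast")
#' img  <- make_phantom(spec)
#' @export
phantom_spec <- function(kind = c("catphan_lowcontrast", "wire", "water"),
                         background_hu = NULL,
                         disk_contrast_hu = 10,
                         disk_diameter_mm = 10,
                         wire_offset_mm = c(5, 5),
                         wire_fwhm_mm = 0.15,
                         wire_hu_mm2 = 1000,
                         field_of_view_mm = NULL,
                         grid_size = 256) {
  kind <- match.arg(kind)
  if (is.null(field_of_view_mm))
    field_of_view_mm <- switch(kind, catphan_lowcontrast = 250, wire = 50, water = 200)
  if (is.null(background_hu))
    background_hu <- switch(kind, catphan_lowcontrast = 63.4, wire = 0, water = 0)
  grid_size <- as.integer(grid_size)
  if (grid_size < 8L) stop("grid_size too small")
  if (field_of_view_mm <= 0) stop("field_of_view_mm must be > 0")
  if (kind == "catphan_lowcontrast") {
    if (disk_diameter_mm <= 0) stop("disk_diameter_mm must be > 0")
    if (disk_diameter_mm >= field_of_view_mm)
      stop("disk larger than the field of view")
  }
  if (kind == "wire") {
    if (length(wire_offset_mm) != 2L) stop("wire_offset_mm must be length 2")
    if (max(abs(wire_offset_mm)) >= field_of_view_mm / 2)
      stop("wire offset outside the field of view")
    if (wire_fwhm_mm <= 0) stop("wire_fwhm_mm must be > 0")
  }
  structure(
    list(kind = kind, background_hu = background_hu,
         disk_contrast_hu = disk_contrast_hu,
         disk_diameter_mm = disk_diameter_mm,
         wire_offset_mm = as.numeric(wire_offset_mm),
         wire_fwhm_mm = wire_fwhm_mm, wire_hu_mm2 = wire_hu_mm2,
         field_of_view_mm = field_of_view_mm, grid_size = grid_size),
    class = "phantom_spec"
  )
}

#' Acquisition and noise-model parameters
#'
#' Collects the scan parameters the noise model depends on. Image noise SD
#' scales with tube current-time product as `sigma = sigma_ref_hu *
#' sqrt(reference_mas / mas_per_rot)`; an iterative-reconstruction-like
#' flavor multiplies the noise by `ir_noise_scale` (< 1). Noise in phases
#' separated by less than the temporal reconstruction window is correlated
#' because the windows share projection data; the correlation at lag `d` is
#' the triangular overlap `max(0, 1 - d / window_ms)`.
#'
#' @param mas_per_rot tube current-time product of the scan, mAs/rot.
#' @param reference_mas calibration dose at which `sigma_ref_hu` applies.
#' @param rotation_ms gantry rotation time, ms. A 280 ms dual-source
#'   rotation with half reconstruction implies a ~70 ms temporal window.
#' @param window_ms temporal reconstruction-window length, ms.
#' @param sigma_ref_hu noise SD (HU) of a single FBP-like phase at the
#'   reference dose.
#' @param kernel_sigma_mm Gaussian system point-spread-function width
#'   (standard deviation, mm) of the reconstruction kernel.
#' @param recon_flavor `"FBP_like"` or `"IR_like"`.
#' @param ir_noise_scale multiplicative noise factor of the IR-like flavor.
#'   The default 1.18/1.25 matches the measured FBP:IR single-phase CNR
#'   ratio the bench is calibrated to.
#' @param noise_colored if `TRUE`, noise fields are colored by the system
#'   kernel and rescaled back to the target SD; default is white noise added
#'   after the blur.
#' @param scan_jitter_rel relative SD of the per-scan noise level
#'   (tube-output / calibration variation between replicate scans; one
#'   multiplicative factor per simulated series). `0` gives the exact
#'   dose-law noise model; the study drivers use 0.02, which reproduces the
#'   replicate scatter of repeated phantom scans.
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(mas_per_rot = 456,
                               reference_mas = 456,
                               rotation_ms = 280,
                               window_ms = 70,
                               sigma_ref_hu = 10 / 1.18,
                               kernel_sigma_mm = 0.62,
                               recon_flavor = c("FBP_like", "IR_like"),
                               ir_noise_scale = 1.18 / 1.25,
                               noise_colored = FALSE,
                               scan_jitter_rel = 0) {
  recon_flavor <- match.arg(recon_flavor)
  if (mas_per_rot <= 0 || reference_mas <= 0) stop("doses must be > 0")
  if (rotation_ms <= 0) stop("rotation_ms must be > 0")
  if (window_ms <= 0) stop("window_ms must be > 0")
  if (sigma_ref_hu < 0) stop("sigma_ref_hu must be >= 0")
  if (kernel_sigma_mm < 0) stop("kernel_sigma_mm must be >= 0")
  if (ir_noise_scale <= 0 || ir_noise_scale > 1)
    stop("ir_noise_scale must be in (0, 1]")
  if (scan_jitter_rel < 0 || scan_jitter_rel >= 0.5)
    stop("scan_jitter_rel must be in [0, 0.5)")
  structure(
    list(mas_per_rot = mas_per_rot, reference_mas = reference_mas,
         rotation_ms = rotation_ms, window_ms = window_ms,
         sigma_ref_hu = sigma_ref_hu, kernel_sigma_mm = kernel_sigma_mm,
         recon_flavor = recon_flavor, ir_noise_scale = ir_noise_scale,
         noise_colored = isTRUE(noise_colored),
         scan_jitter_rel = scan_jitter_rel),
    class = "acquisition_params"
  )
}

ir_factor <- function(acq) {
  if (acq$recon_flavor == "IR_like") acq$ir_noise_scale else 1
}

#' Effective single-phase noise SD of an acquisition
#'
#' `sigma_ref_hu * sqrt(reference_mas / mas_per_rot)`, times
#' `ir_noise_scale` for the IR-like flavor.
#'
#' @param acq an [acquisition_params] object.
#' @return noise SD in HU.
#' @export
noise_sigma <- function(acq) {
  acq$sigma_ref_hu * sqrt(acq$reference_mas / acq$mas_per_rot) * ir_factor(acq)
}

#' Render a noiseless digital phantom
#'
#' Produces the noiseless ground-truth image for a [phantom_spec]: the
#' low-contrast slice is a uniform background plus one anti-aliased disk
#' (4x4 sub-pixel coverage at the rim); the wire slice is a sub-pixel
#' Gaussian impulse of fixed line integral centred at the wire offset; the
#' water slice is a uniform field. The system blur is not applied here - it
#' belongs to the acquisition model in [simulate_series()].
#'
#' @param spec a [phantom_spec].
#' @return a [phase_image] at phase 0.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  n <- spec$grid_size
  h <- spec$field_of_view_mm / n
  img <- phase_image(matrix(spec$background_hu, n, n), spacing_mm = h)
  co <- pixel_coords(img)
  if (spec$kind == "water") return(img)
  if (spec$kind == "catphan_lowcontrast") {
    r <- spec$disk_diameter_mm / 2
    # 4x4 sub-pixel coverage fraction of the disk, anti-aliasing the rim
    sub <- (seq_len(4) - 2.5) / 4 * h
    cov <- matrix(0, n, n)
    for (dy in sub) for (dx in sub) {
      cov <- cov + (outer((co$y + dy)^2, (co$x + dx)^2, `+`) <= r^2)
    }
    img$pixels <- img$pixels + spec$disk_contrast_hu * cov / 16
    return(img)
  }
  # wire: Gaussian impulse at the offset, area-normalized to the line integral
  sw <- spec$wire_fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- outer((co$y - spec$wire_offset_mm[2])^2,
              (co$x - spec$wire_offset_mm[1])^2, `+`)
  g <- exp(-d2 / (2 * sw^2))
  s <- sum(g) * h^2
  if (s <= 0) stop("wire impulse vanished on this grid")
  img$pixels <- img$pixels + g * (spec$wire_hu_mm2 / s)
  img
}

#' Calibrate the reference noise scale
#'
#' Fixes the free noise scale `sigma_ref_hu` so that a single phase at the
#' reference dose reproduces, in expectation, a requested contrast-to-noise
#' ratio (`sigma = contrast / CNR`), noise SD (`sigma = value`), or
#' two-independent-frame MSE plateau (`sigma = sqrt(value / 2)`). For an
#' IR-like acquisition the returned reference scale is divided by
#' `ir_noise_scale` so the target is met after IR scaling.
#'
#' @param target one of `"cnr"`, `"sd"`, `"mse_plateau"`.
#' @param value the target value; must be > 0.
#' @param spec a [phantom_spec] (supplies the disk contrast for `"cnr"`).
#' @param acq an [acquisition_params].
#' @return the calibrated `sigma_ref_hu` (HU).
#' @examples
#' sp <- phantom_spec("catphan_lowcontrast")
#' calibrate_noise("cnr", 1.18, sp, acquisition_params())  # 10 / 1.18
#' @export
calibrate_noise <- function(target = c("cnr", "sd", "mse_plateau"), value,
                            spec, acq = acquisition_params()) {
  target <- match.arg(target)
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("target value must be a single positive number")
  sigma <- switch(target,
    cnr = {
      if (spec$disk_contrast_hu <= 0)
        stop("cnr calibration requires disk_contrast_hu > 0")
      spec$disk_contrast_hu / value
    },
    sd = value,
    mse_plateau = sqrt(value / 2)
  )
  sigma / ir_factor(acq)
}

# greatest common divisor of two durations on a 0.1 ms lattice
time_gcd_ms <- function(a, b) {
  ia <- round(a * 10); ib <- round(b * 10)
  if (abs(a * 10 - ia) > 1e-6 || abs(b * 10 - ib) > 1e-6)
    stop("interval and window must be multiples of 0.1 ms")
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  g(ia, ib) / 10
}

#' Simulate a replicate phase series with correlated noise
#'
#' Each frame is the system-blurred ground truth plus a zero-mean Gaussian
#' noise field of per-pixel SD [noise_sigma()]. Noise in frames whose
#' reconstruction windows overlap is correlated: frame `i`'s field is the
#' mean of `window_ms / step` white fields drawn from a common time-indexed
#' pool (step = gcd of interval and window), scaled by `1/sqrt(n steps)`,
#' which yields exactly the triangular correlation
#' `rho(lag) = max(0, 1 - lag / window_ms)` between frames. With
#' `noise_colored = TRUE` each field is additionally colored by the system
#' kernel and rescaled to the target SD. The result is deterministic under a
#' fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param acq an [acquisition_params].
#' @param n_phases number of phases (>= 1).
#' @param interval_ms phase spacing, ms (> 0); must be commensurate with
#'   `window_ms` on a 0.1 ms lattice.
#' @param seed integer seed for the noise stream, or `NULL`.
#' @return a [phase_series] with phase times centred on 0 ms and the
#'   (unblurred) ground truth attached.
#' @export
simulate_series <- function(spec, acq = acquisition_params(), n_phases = 3,
                            interval_ms = 50, seed = NULL) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L) stop("n_phases must be >= 1")
  if (interval_ms <= 0) stop("interval_ms must be > 0")
  gt <- make_phantom(spec)
  blurred <- gaussian_blur(gt$pixels, acq$kernel_sigma_mm, gt$spacing_mm)
  sig <- noise_sigma(acq)
  d <- dim(blurred)
  tms <- (seq_len(n_phases) - (n_phases + 1) / 2) * interval_ms

  if (sig == 0) {
    frames <- lapply(tms, function(t) phase_image(blurred, gt$spacing_mm, t))
    return(phase_series(frames, interval_ms, ground_truth = gt, seed = seed))
  }

  step <- time_gcd_ms(interval_ms, acq$window_ms)
  nwin <- as.integer(round(acq$window_ms / step))
  hop <- as.integer(round(interval_ms / step))
  npool <- (n_phases - 1L) * hop + nwin
  npix <- prod(d)

  frames <- with_seed(seed, {
    # one multiplicative noise-level factor per scan (replicate series)
    sig_scan <- if (acq$scan_jitter_rel > 0)
      sig * max(1 + stats::rnorm(1) * acq$scan_jitter_rel, 0.5) else sig
    pool <- matrix(stats::rnorm(npix * npool), nrow = npix, ncol = npool)
    lapply(seq_len(n_phases), function(i) {
      idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + nwin)
      fld <- if (nwin == 1L) pool[, idx] else rowSums(pool[, idx, drop = FALSE])
      fld <- matrix(fld / sqrt(nwin), d[1], d[2])
      if (acq$noise_colored) {
        fld <- gaussian_blur(fld, acq$kernel_sigma_mm, gt$spacing_mm)
        fld <- fld / blur_noise_gain(acq$kernel_sigma_mm, d, gt$spacing_mm)
      }
      phase_image(blurred + sig_scan * fld, gt$spacing_mm, tms[i])
    })
  })
  phase_series(frames, interval_ms, ground_truth = gt, seed = seed)
}
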