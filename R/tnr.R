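#' Parameters of the legato temporal noise-reduction filter
#'
#' The filter averages each phase with its two temporal neighbors after
#' registration: the center phase gets weight `1 - 2 * neighbor_weight` and
#' each adjacent phase `neighbor_weight` (default 0.3, i.e. weights
#' 0.3 / 0.4 / 0.3). With the non-cyclic boundary rule (`cyclic = FALSE`) a
#' missing neighbor's weight is dropped and the remaining weights are
#' renormalized to sum to one, so edge phases stay unbiased.
#'
#' @param neighbor_weight weight of each adjacent phase, in `[0, 0.5]`.
#' @param interp_factor number of interpolated phases generated between
#'   consecutive originals (the "x1" setting generates one).
#' @param cyclic if `TRUE`, the phase axis wraps around (cardiac-cycle
#'   periodicity); the bench default is the non-cyclic rule.
#' @param registration `"identity"` (static phantoms) or `"translation"`
#'   (integer-pixel cross-correlation shift) - the registration hook.
#' @param include_interpolated whether interpolated phases enter the
#'   average. Linear interpolants of the originals add no independent
#'   information, so the default excludes them.
#' @return object of class `legato_params`.
#' @export
legato_params <- function(neighbor_weight = 0.3, interp_factor = 1,
                          cyclic = FALSE,
                          registration = c("identity", "translation"),
                          include_interpolated = FALSE) {
  registration <- match.arg(registration)
  if (neighbor_weight < 0 || neighbor_weight > 0.5)
    stop("neighbor_weight must lie in [0, 0.5]")
  interp_factor <- as.integer(interp_factor)
  if (interp_factor < 0) stop("interp_factor must be >= 0")
  structure(
    list(neighbor_weight = neighbor_weight, interp_factor = interp_factor,
         cyclic = isTRUE(cyclic), registration = registration,
         include_interpolated = isTRUE(include_interpolated)),
    class = "legato_params"
  )
}

#' Register one phase image to another
#'
#' The registration hook of the filter. `identity` mode returns a zero
#' displacement (appropriate for static phantoms); `translation` mode
#' estimates the integer-pixel shift maximizing the circular
#' cross-correlation between the images. The commercial filter's non-rigid
#' registration is deliberately not reproduced.
#'
#' @param moving,fixed [phase_image] objects on the same grid.
#' @param mode `"identity"` or `"translation"`.
#' @return object of class `displacement` with the pixel shift
#'   `shift_px = c(rows, cols)` by which `moving` is displaced relative to
#'   `fixed`; [apply_displacement()] undoes it.
#' @export
register_pair <- function(moving, fixed, mode = c("identity", "translation")) {
  mode <- match.arg(mode)
  if (!identical(dim(moving$pixels), dim(fixed$pixels)))
    stop("moving and fixed must share the grid shape")
  if (mode == "identity")
    return(structure(list(shift_px = c(0L, 0L), mode = mode),
                     class = "displacement"))
  a <- moving$pixels - mean(moving$pixels)
  b <- fixed$pixels - mean(fixed$pixels)
  d <- dim(a)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  k <- which.max(cc)
  sh <- c((k - 1L) %% d[1], (k - 1L) %/% d[1])
  sh <- ifelse(sh > dim(a) / 2, sh - dim(a), sh)
  structure(list(shift_px = as.integer(-sh), mode = mode),
            class = "displacement")
}

#' Apply a displacement to a phase image
#'
#' Resamples the image by the stored integer-pixel shift with edge
#' replication (non-circular).
#'
#' @param image a [phase_image].
#' @param disp a `displacement` from [register_pair()].
#' @return the resampled [phase_image].
#' @export
apply_displacement <- function(image, disp) {
  sh <- disp$shift_px
  if (all(sh == 0L)) return(image)
  d <- dim(image$pixels)
  ri <- pmin(pmax(seq_len(d[1]) + sh[1], 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) + sh[2], 1L), d[2])
  out <- image
  out$pixels <- image$pixels[ri, ci]
  out
}

#' Interpolate an intermediate phase
#'
#' Registers `b` onto `a` and returns the linear blend
#' `(1 - alpha) * a + alpha * b_registered`, with the phase time
#' interpolated linearly.
#'
#' @param a,b [phase_image] objects on the same grid.
#' @param alpha blend fraction in `[0, 1]` (0 returns `a`).
#' @param registration registration mode passed to [register_pair()].
#' @return the interpolated [phase_image].
#' @export
interpolate_phase <- function(a, b, alpha, registration = "identity") {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("a and b must share the grid shape")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  br <- apply_displacement(b, register_pair(b, a, registration))
  phase_image((1 - alpha) * a$pixels + alpha * br$pixels,
              a$spacing_mm,
              (1 - alpha) * a$phase_ms + alpha * b$phase_ms)
}

# weighted average of frames[center +/- 1] registered to the center frame;
# missing neighbors are dropped and weights renormalized (non-cyclic), or
# wrapped around (cyclic)
filter_core <- function(frames, center, w, registration, cyclic) {
  n <- length(frames)
  idx <- center + c(-1L, 0L, 1L)
  wts <- c(w, 1 - 2 * w, w)
  if (cyclic && n > 1L) {
    idx <- ((idx - 1L) %% n) + 1L
  } else {
    keep <- idx >= 1L & idx <= n
    idx <- idx[keep]; wts <- wts[keep]
  }
  wts <- wts / sum(wts)
  ref <- frames[[center]]
  acc <- matrix(0, nrow(ref$pixels), ncol(ref$pixels))
  for (k in seq_along(idx)) {
    f <- frames[[idx[k]]]
    if (idx[k] != center)
      f <- apply_displacement(f, register_pair(f, ref, registration))
    acc <- acc + wts[k] * f$pixels
  }
  phase_image(acc, ref$spacing_mm, ref$phase_ms)
}

#' Weighted temporal averaging of a phase series
#'
#' Averages the center phase with its two temporal neighbors (registered to
#' the center) using weights `neighbor_weight` / `1 - 2*neighbor_weight` /
#' `neighbor_weight`. With the non-cyclic rule, a missing neighbor's weight
#' is dropped and the rest renormalized; a single-frame series is returned
#' unchanged. Mean attenuation is preserved in expectation because the
#' weights sum to one.
#'
#' @param series a [phase_series].
#' @param params a [legato_params].
#' @param center explicit center index (required for even-length series).
#' @return the filtered center [phase_image].
#' @export
temporal_filter <- function(series, params = legato_params(), center = NULL) {
  ci <- center_index(series, center)
  filter_core(series$frames, ci, params$neighbor_weight,
              params$registration, params$cyclic)
}

#' Apply the legato temporal noise-reduction pipeline
#'
#' Pipeline: optionally generate `interp_factor` interpolated phases between
#' consecutive originals, register all phases to the center phase, and apply
#' the weighted temporal average. Returns the denoised center-phase image
#' tagged with its phase time. When interpolated phases are excluded from
#' the average (the default) their generation is elided, since they would
#' not contribute.
#'
#' @param series a [phase_series] (3 phases in the standard configuration,
#'   any odd length accepted).
#' @param params a [legato_params].
#' @param center explicit center index for even-length series.
#' @return the denoised center [phase_image].
#' @examples
#' sp  <- phantom_spec("water", grid_size = 64)
#' ser <- simulate_series(sp, acquisition_params(sigma_ref_hu = 5),
#'                        n_phases = 3, interval_ms = 90, seed = 1)
#' out <- legato(ser)
#' @export
legato <- function(series, params = legato_params(), center = NULL) {
  ci <- center_index(series, center)
  frames <- series$frames
  if (params$interp_factor > 0L && params$include_interpolated) {
    ext <- list(frames[[1]])
    for (i in seq_len(length(frames) - 1L)) {
      for (k in seq_len(params$interp_factor)) {
        al <- k / (params$interp_factor + 1)
        ext[[length(ext) + 1L]] <-
          interpolate_phase(frames[[i]], frames[[i + 1L]], al,
                            params$registration)
      }
      ext[[length(ext) + 1L]] <- frames[[i + 1L]]
    }
    frames <- ext
    ci <- (ci - 1L) * (params$interp_factor + 1L) + 1L
  }
  filter_core(frames, ci, params$neighbor_weight,
              params$registration, params$cyclic)
}
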