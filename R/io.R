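#' Export a phase series as NIfTI files with a JSON sidecar
#'
#' Writes one NIfTI file per phase (`phase_001.nii.gz`, ...; pixel spacing
#' in the header) plus `series.json` carrying the phase times, interval and
#' seed.
#'
#' @param series a [phase_series].
#' @param dir output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(series$frames))
  for (i in seq_along(series$frames)) {
    f <- series$frames[[i]]
    files[i] <- sprintf("phase_%03d.nii.gz", i)
    vol <- RNifti::asNifti(f$pixels)
    RNifti::pixdim(vol) <- f$spacing_mm
    RNifti::writeNifti(vol, file.path(dir, files[i]))
  }
  sidecar <- list(
    files = files,
    phase_ms = vapply(series$frames, function(f) f$phase_ms, numeric(1)),
    interval_ms = series$interval_ms,
    spacing_mm = series$frames[[1]]$spacing_mm,
    seed = series$seed
  )
  path <- file.path(dir, "series.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a phase series written by [write_series()]
#'
#' @param dir directory containing the NIfTI phases and `series.json`.
#' @return a [phase_series] (without ground truth).
#' @export
read_series <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "series.json"),
                            simplifyVector = TRUE)
  frames <- lapply(seq_along(sc$files), function(i) {
    vol <- RNifti::readNifti(file.path(dir, sc$files[i]))
    a <- as.array(vol)
    pix <- matrix(as.numeric(a), dim(a)[1], dim(a)[2])
    sp <- RNifti::pixdim(vol)[1:2]
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- sc$spacing_mm
    phase_image(pix, sp, sc$phase_ms[i])
  })
  phase_series(frames, sc$interval_ms,
               seed = if (is.null(sc$seed)) NULL else sc$seed)
}

as_config_list <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a phantom + acquisition configuration file
#'
#' Reads a YAML or JSON file with top-level keys `phantom` (fields of
#' [phantom_spec()]) and `acquisition` (fields of [acquisition_params()]).
#'
#' @param path path to the YAML or JSON file.
#' @return list with elements `phantom` and `acquisition`.
#' @export
read_phantom_config <- function(path) {
  cfg <- as_config_list(path)
  list(phantom = do.call(phantom_spec, cfg$phantom %||% list()),
       acquisition = do.call(acquisition_params, cfg$acquisition %||% list()))
}

#' Read a study configuration file
#'
#' Reads a YAML or JSON file whose keys are [study_config()] arguments; the
#' `legato` key, if present, holds [legato_params()] arguments.
#'
#' @param path path to the YAML or JSON file.
#' @return a [study_config].
#' @export
read_study_config <- function(path) {
  cfg <- as_config_list(path)
  if (!is.null(cfg$legato)) cfg$legato <- do.call(legato_params, cfg$legato)
  do.call(study_config, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read ROI definitions from a JSON file
#'
#' The file is a JSON list of objects with fields `center_mm`, `radius_mm`
#' and `role`.
#'
#' @param path path to the JSON file.
#' @return list of [roi_spec] objects, named by role where unique.
#' @export
read_rois <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(lst, function(r)
    roi_spec(unlist(r$center_mm), r$radius_mm, r$role))
  roles <- vapply(rois, function(r) r$role, character(1))
  if (!anyDuplicated(roles)) names(rois) <- roles
  rois
}

#' Export an MTF or NPS curve as CSV
#'
#' Two columns: frequency (cycles/mm) and value (unitless MTF or
#' HU^2 mm^2 NPS).
#'
#' @param curve an `mtf_curve` or `nps_curve`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_curve_csv <- function(curve, path) {
  df <- if (inherits(curve, "mtf_curve"))
    data.frame(frequency_cycles_mm = curve$frequencies, value = curve$values)
  else if (inherits(curve, "nps_curve"))
    data.frame(frequency_cycles_mm = curve$radial_frequencies,
               value = curve$values)
  else stop("curve must be an mtf_curve or nps_curve")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-replicate metric table
#'
#' Reads a CSV with columns `condition`, `replicate`, `metric`, `value` —
#' the long format the study reports write — for feeding the statistics
#' layer.
#'
#' @param path CSV path.
#' @return data frame with the four columns.
#' @seealso [metric_groups()] to split it for [tukey_kramer()].
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "metric", "value")
  if (!all(need %in% names(df)))
    stop("metric CSV needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Split a metric table into per-condition sample vectors
#'
#' @param metrics data frame as returned by [read_metrics_csv()].
#' @param metric which metric to extract.
#' @return named list of numeric vectors, one per condition, ready for
#'   [tukey_kramer()].
#' @export
metric_groups <- function(metrics, metric) {
  sub <- metrics[metrics$metric == metric, ]
  if (!nrow(sub)) stop("no rows for metric: ", metric)
  split(sub$value, sub$condition)
}

#' Extract a 2D slice from a NIfTI volume as a phase image
#'
#' Entry point for running the metric suite on real volumes.
#'
#' @param path NIfTI file path.
#' @param slice slice index along the third axis (ignored for 2D volumes).
#' @param phase_ms phase time to tag the image with.
#' @return a [phase_image].
#' @export
read_nifti_slice <- function(path, slice = 1L, phase_ms = 0) {
  vol <- RNifti::readNifti(path)
  a <- as.array(vol)
  pix <- if (length(dim(a)) >= 3L) a[, , slice] else a
  pix <- matrix(as.numeric(pix), dim(pix)[1], dim(pix)[2])
  sp <- RNifti::pixdim(vol)[1:2]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header lacks a positive pixel spacing")
  phase_image(pix, sp, phase_ms)
}
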