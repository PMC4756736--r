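#' Configuration of one phantom study
#'
#' Three studies are orchestrated end to end (simulate, filter, measure,
#' test): `"preliminary"` (CNR and inter-phase MSE across interval times
#' 10-90 ms under the triangular 70 ms reconstruction-window correlation),
#' `"quantitative"` (CT value, CNR, wire MTF and water NPS at the base dose
#' for FBP-like and IR-like noise, 50 ms interval), and `"dose_reduction"`
#' (reference vs quarter dose vs quarter dose + filter, IR-like). In the
#' quantitative and dose-reduction studies the three 50 ms-separated phases
#' carry independent noise (window set to the interval), matching the
#' measured CNR plateau at 50 ms; the preliminary study keeps the 70 ms
#' window, which the measured MSE-interval curve follows.
#'
#' @param study `"preliminary"`, `"quantitative"` or `"dose_reduction"`.
#' @param n_replicates replicate scans per condition (>= 2; default 10, the
#'   replication the bench models).
#' @param intervals_ms phase intervals, ms.
#' @param doses_mas tube current-time products, mAs/rot.
#' @param calibration named list fixing the free scales: `cnr` (single-phase
#'   CNR at reference dose), `sd` (noise SD, HU), `mse_plateau`
#'   (decorrelated two-frame MSE, HU^2), `mtf10` (single-frame MTF10%,
#'   cycles/mm, fixes the kernel width).
#' @param seed master seed; replicate streams are derived by a fixed
#'   counter scheme.
#' @param legato a [legato_params].
#' @param grid_size phantom grid, pixels per side.
#' @param window_ms reconstruction-window length for the noise correlation.
#' @param scan_jitter_rel relative per-scan noise-level variation passed to
#'   [acquisition_params()]; the default 0.02 reproduces the replicate
#'   scatter of repeated phantom scans.
#' @param alpha significance level.
#' @return object of class `study_config`.
#' @export
study_config <- function(study = c("preliminary", "quantitative",
                                   "dose_reduction"),
                         n_replicates = 10, intervals_ms = NULL,
                         doses_mas = NULL, calibration = NULL, seed = 1,
                         legato = legato_params(), grid_size = 256,
                         window_ms = NULL, scan_jitter_rel = 0.02,
                         alpha = 0.05) {
  study <- match.arg(study)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (is.null(intervals_ms))
    intervals_ms <- if (study == "preliminary") c(10, 30, 50, 70, 90) else 50
  if (is.null(doses_mas))
    doses_mas <- if (study == "dose_reduction") c(456, 114) else 456
  if (is.null(window_ms))
    window_ms <- if (study == "preliminary") 70 else intervals_ms[1]
  if (is.null(calibration))
    calibration <- switch(study,
      preliminary = list(mse_plateau = 151.0),
      quantitative = list(cnr = 1.18, mtf10 = 0.55),
      dose_reduction = list(cnr = 1.25))
  if (study == "preliminary" && length(intervals_ms) < 2L)
    stop("preliminary study needs at least 2 intervals")
  if (study == "dose_reduction" && length(doses_mas) < 2L)
    stop("dose-reduction study needs at least 2 doses")
  structure(
    list(study = study, n_replicates = n_replicates,
         intervals_ms = intervals_ms, doses_mas = doses_mas,
         calibration = calibration, seed = as.integer(seed),
         legato = legato, grid_size = as.integer(grid_size),
         window_ms = window_ms, scan_jitter_rel = scan_jitter_rel,
         alpha = alpha),
    class = "study_config"
  )
}

# independent per-replicate seed derived from the master seed by a fixed
# counter scheme (stream = condition counter, rep = replicate counter)
replicate_seed <- function(master, stream, rep) {
  as.integer(((as.double(master) * 100003 + stream * 1009 + rep) %%
                2147483629) + 1)
}

# default measurement ROIs for the low-contrast slice
default_rois <- function() {
  list(target = roi_spec(c(0, 0), 4, "target"),
       background = roi_spec(c(25, 0), 10, "background"))
}

resolve_sigma_ref <- function(calibration, spec, acq) {
  for (nm in c("cnr", "sd", "mse_plateau")) {
    if (!is.null(calibration[[nm]]))
      return(calibrate_noise(nm, calibration[[nm]], spec, acq))
  }
  stop("calibration must fix the noise scale (cnr, sd or mse_plateau)")
}

fnv_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%010d", h)
}

study_report <- function(study, config, metrics, stats_list,
                         extras = list()) {
  agg <- stats::aggregate(value ~ condition + metric, data = metrics,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  summary_df <- data.frame(condition = agg$condition, metric = agg$metric,
                           mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                           n = agg$value[, "n"], stringsAsFactors = FALSE)
  summary_df <- summary_df[order(summary_df$metric, summary_df$condition), ]
  rownames(summary_df) <- NULL
  structure(
    list(study = study, config = config, metrics = metrics,
         summary = summary_df, stats = stats_list, extras = extras,
         provenance = list(config_hash = fnv_hash(unclass(config)),
                           seed = config$seed,
                           version = as.character(utils::packageVersion("legatoCT")))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s study, %d replicates, seed %d (config %s)\n\n",
              x$study, x$config$n_replicates, x$config$seed,
              x$provenance$config_hash))
  s <- x$summary
  s$mean <- sprintf("%.3f", s$mean)
  s$sd <- sprintf("%.3f", s$sd)
  print(s, row.names = FALSE)
  if (length(x$stats)) {
    cat("\nComparisons:\n")
    for (r in x$stats) print(r)
  }
  if (!is.null(x$extras$plateau_ms))
    cat(sprintf("\nCNR plateau interval: %g ms\n", x$extras$plateau_ms))
  invisible(x)
}

#' Run the preliminary interval-time study
#'
#' For each interval time, over seeded replicate three-phase series of the
#' low-contrast phantom: the CNR of the filtered center phase and the
#' per-pixel MSE between the two phases separated by that interval (raw
#' frames, as a proxy for inter-phase noise independence). Reports
#' per-interval means and SDs, Tukey-Kramer comparisons of the MSE across
#' intervals, and the CNR plateau interval (smallest interval whose mean
#' CNR is within one pooled SD of the maximum).
#'
#' @param config a `"preliminary"` [study_config].
#' @return a `study_report`.
#' @export
run_preliminary <- function(config = study_config("preliminary")) {
  if (config$study != "preliminary") stop("config is not a preliminary study")
  spec <- phantom_spec("catphan_lowcontrast", grid_size = config$grid_size)
  acq0 <- acquisition_params(window_ms = config$window_ms)
  acq <- acquisition_params(window_ms = config$window_ms,
                            sigma_ref_hu = resolve_sigma_ref(config$calibration,
                                                             spec, acq0),
                            scan_jitter_rel = config$scan_jitter_rel)
  rois <- default_rois()
  rows <- list()
  for (ii in seq_along(config$intervals_ms)) {
    iv <- config$intervals_ms[ii]
    for (rep in seq_len(config$n_replicates)) {
      ser <- simulate_series(spec, acq, n_phases = 3, interval_ms = iv,
                             seed = replicate_seed(config$seed, ii, rep))
      den <- legato(ser, config$legato)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = sprintf("interval_%gms", iv), replicate = rep,
        metric = c("cnr_legato", "mse_pair"),
        value = c(cnr(den, rois$target, rois$background),
                  mse(ser$frames[[1]], ser$frames[[2]])))
    }
  }
  metrics <- do.call(rbind, rows)

  mse_groups <- split(metrics$value[metrics$metric == "mse_pair"],
                      metrics$condition[metrics$metric == "mse_pair"])
  stats_list <- tukey_kramer(mse_groups, alpha = config$alpha)

  cm <- metrics[metrics$metric == "cnr_legato", ]
  mns <- tapply(cm$value, cm$condition, mean)
  sds <- tapply(cm$value, cm$condition, stats::sd)
  pooled <- sqrt(mean(sds^2))
  ord <- order(config$intervals_ms)
  lab <- sprintf("interval_%gms", config$intervals_ms[ord])
  ok <- mns[lab] >= max(mns) - pooled
  plateau <- config$intervals_ms[ord][which(ok)[1]]

  study_report("preliminary", config, metrics, stats_list,
               extras = list(plateau_ms = plateau))
}

# simulate one catphan replicate and measure reference (center frame) and
# filtered metrics
catphan_pair_metrics <- function(spec, acq, interval_ms, seed, lp, rois) {
  ser <- simulate_series(spec, acq, n_phases = 3, interval_ms = interval_ms,
                         seed = seed)
  ref <- ser$frames[[center_index(ser)]]
  den <- legato(ser, lp)
  c(ct_reference = mean(ref$pixels[roi_mask(ref, rois$background)]),
    ct_legato = mean(den$pixels[roi_mask(den, rois$background)]),
    cnr_reference = cnr(ref, rois$target, rois$background),
    cnr_legato = cnr(den, rois$target, rois$background))
}

#' Run the quantitative image-quality study
#'
#' Produces the base-dose comparison of filtered versus reference images:
#' CT-attenuation equivalence (2 HU margin) and CNR (Tukey-Kramer plus
#' non-inferiority at margin 0.1) on the low-contrast slice for both
#' FBP-like and IR-like noise; wire-method MTF10% non-inferiority (margin
#' 0.05 cycles/mm) with the kernel width calibrated to the single-frame
#' MTF10% target; and reference vs filtered radial NPS curves from the
#' water slice, with the per-bin NPS ratio summarized to check that noise
#' is reduced uniformly across the frequency band. The CT attenuation is
#' measured in the uniform background ROI.
#'
#' @param config a `"quantitative"` [study_config].
#' @return a `study_report`; NPS curves and the per-bin ratio are in
#'   `$extras`.
#' @export
run_quantitative <- function(config = study_config("quantitative")) {
  if (config$study != "quantitative") stop("config is not a quantitative study")
  iv <- config$intervals_ms[1]
  rois <- default_rois()
  cat_spec <- phantom_spec("catphan_lowcontrast", grid_size = config$grid_size)
  sigma_ref <- resolve_sigma_ref(config$calibration, cat_spec,
                                 acquisition_params())
  lp <- config$legato
  rows <- list(); stats_list <- list()

  for (fi in seq_along(c("FBP_like", "IR_like"))) {
    flavor <- c("FBP_like", "IR_like")[fi]
    acq <- acquisition_params(window_ms = config$window_ms,
                              sigma_ref_hu = sigma_ref, recon_flavor = flavor,
                              scan_jitter_rel = config$scan_jitter_rel)
    vals <- vapply(seq_len(config$n_replicates), function(rep)
      catphan_pair_metrics(cat_spec, acq, iv,
                           replicate_seed(config$seed, fi, rep), lp, rois),
      numeric(4))
    tag <- if (flavor == "FBP_like") "FBP" else "IR"
    for (m in rownames(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = tag, replicate = seq_len(config$n_replicates),
        metric = m, value = vals[m, ])
    }
    stats_list[[length(stats_list) + 1L]] <- equivalence_test(
      vals["ct_legato", ] - vals["ct_reference", ], margin = 2,
      comparison = sprintf("%s CT value legato - reference (HU)", tag))
    stats_list <- c(stats_list, tukey_kramer(
      stats::setNames(list(vals["cnr_reference", ], vals["cnr_legato", ]),
                      paste0(tag, c("_reference", "_legato"))),
      alpha = config$alpha))
    stats_list[[length(stats_list) + 1L]] <- noninferiority_test(
      vals["cnr_legato", ], vals["cnr_reference", ], margin = 0.1,
      paired = TRUE,
      comparison = sprintf("%s CNR legato vs reference", tag))
  }

  # wire phantom: MTF10% of reference vs filtered images
  wire_spec <- phantom_spec("wire", grid_size = config$grid_size)
  mtf10_target <- if (!is.null(config$calibration$mtf10))
    config$calibration$mtf10 else 0.55
  ks <- calibrate_kernel(mtf10_target, wire_spec)
  wacq <- acquisition_params(window_ms = config$window_ms,
                             sigma_ref_hu = sigma_ref, kernel_sigma_mm = ks,
                             scan_jitter_rel = config$scan_jitter_rel)
  mtf_ref <- mtf_leg <- numeric(config$n_replicates)
  for (rep in seq_len(config$n_replicates)) {
    ser <- simulate_series(wire_spec, wacq, n_phases = 3, interval_ms = iv,
                           seed = replicate_seed(config$seed, 11L, rep))
    ref <- ser$frames[[center_index(ser)]]
    den <- legato(ser, lp)
    mtf_ref[rep] <- mtf_wire(ref, wire_spec$wire_offset_mm)$mtf10
    mtf_leg[rep] <- mtf_wire(den, wire_spec$wire_offset_mm)$mtf10
  }
  rows[[length(rows) + 1L]] <- data.frame(
    condition = "wire", replicate = seq_len(config$n_replicates),
    metric = "mtf10_reference", value = mtf_ref)
  rows[[length(rows) + 1L]] <- data.frame(
    condition = "wire", replicate = seq_len(config$n_replicates),
    metric = "mtf10_legato", value = mtf_leg)
  stats_list[[length(stats_list) + 1L]] <- noninferiority_test(
    mtf_leg, mtf_ref, margin = 0.05, paired = TRUE,
    comparison = "MTF10% legato vs reference (cycles/mm)")

  # water phantom: reference vs filtered NPS
  wat_spec <- phantom_spec("water", grid_size = config$grid_size)
  wtacq <- acquisition_params(window_ms = config$window_ms,
                              sigma_ref_hu = sigma_ref,
                              scan_jitter_rel = config$scan_jitter_rel)
  refs <- legs <- vector("list", config$n_replicates)
  for (rep in seq_len(config$n_replicates)) {
    ser <- simulate_series(wat_spec, wtacq, n_phases = 3, interval_ms = iv,
                           seed = replicate_seed(config$seed, 12L, rep))
    refs[[rep]] <- ser$frames[[center_index(ser)]]
    legs[[rep]] <- legato(ser, lp)
  }
  nps_ref <- nps_radial(ensemble_noise_fields(refs))
  nps_leg <- nps_radial(ensemble_noise_fields(legs))
  ratio <- nps_leg$values / nps_ref$values

  study_report("quantitative", config, do.call(rbind, rows), stats_list,
               extras = list(kernel_sigma_mm = ks, nps_reference = nps_ref,
                             nps_legato = nps_leg, nps_ratio = ratio))
}

#' Run the dose-reduction study
#'
#' Compares, for the IR-like flavor, three arms of the low-contrast slice:
#' reference dose without filtering, quarter dose without filtering, and
#' quarter dose with filtering (the two quarter-dose arms share each
#' replicate's series). The quarter-dose noise follows exact
#' `1/sqrt(mAs)` scaling from the calibrated reference. Reports the CNRs
#' with Tukey-Kramer comparisons, non-inferiority tests (margin 0.1) of the
#' filtered quarter-dose arm against both the unfiltered quarter-dose arm
#' and the reference arm, and CT-value equivalence (2 HU margin) of each
#' arm against the reference.
#'
#' @param config a `"dose_reduction"` [study_config].
#' @return a `study_report`.
#' @export
run_dose_reduction <- function(config = study_config("dose_reduction")) {
  if (config$study != "dose_reduction")
    stop("config is not a dose-reduction study")
  iv <- config$intervals_ms[1]
  rois <- default_rois()
  spec <- phantom_spec("catphan_lowcontrast", grid_size = config$grid_size)
  ref_dose <- max(config$doses_mas)
  low_dose <- min(config$doses_mas)
  acq_ref0 <- acquisition_params(mas_per_rot = ref_dose,
                                 reference_mas = ref_dose,
                                 recon_flavor = "IR_like")
  sigma_ref <- resolve_sigma_ref(config$calibration, spec, acq_ref0)
  lp <- config$legato
  mk_acq <- function(dose) acquisition_params(
    mas_per_rot = dose, reference_mas = ref_dose,
    window_ms = config$window_ms, sigma_ref_hu = sigma_ref,
    recon_flavor = "IR_like", scan_jitter_rel = config$scan_jitter_rel)

  n <- config$n_replicates
  ct <- list(reference = numeric(n), quarter = numeric(n),
             quarter_legato = numeric(n))
  cn <- list(reference = numeric(n), quarter = numeric(n),
             quarter_legato = numeric(n))
  for (rep in seq_len(n)) {
    sref <- simulate_series(spec, mk_acq(ref_dose), 3, iv,
                            seed = replicate_seed(config$seed, 21L, rep))
    slow <- simulate_series(spec, mk_acq(low_dose), 3, iv,
                            seed = replicate_seed(config$seed, 22L, rep))
    iref <- sref$frames[[center_index(sref)]]
    ilow <- slow$frames[[center_index(slow)]]
    ileg <- legato(slow, lp)
    for (nm in c("reference", "quarter", "quarter_legato")) {
      img <- switch(nm, reference = iref, quarter = ilow,
                    quarter_legato = ileg)
      ct[[nm]][rep] <- mean(img$pixels[roi_mask(img, rois$background)])
      cn[[nm]][rep] <- cnr(img, rois$target, rois$background)
    }
  }
  rows <- list()
  for (nm in names(cn)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = nm, replicate = seq_len(n), metric = "cnr", value = cn[[nm]])
    rows[[length(rows) + 1L]] <- data.frame(
      condition = nm, replicate = seq_len(n), metric = "ct", value = ct[[nm]])
  }
  stats_list <- tukey_kramer(cn, alpha = config$alpha)
  stats_list[[length(stats_list) + 1L]] <- noninferiority_test(
    cn$quarter_legato, cn$quarter, margin = 0.1, paired = TRUE,
    comparison = "CNR quarter+legato vs quarter")
  stats_list[[length(stats_list) + 1L]] <- noninferiority_test(
    cn$quarter_legato, cn$reference, margin = 0.1, paired = TRUE,
    comparison = "CNR quarter+legato vs reference")
  for (nm in c("quarter", "quarter_legato")) {
    stats_list[[length(stats_list) + 1L]] <- equivalence_test(
      ct[[nm]] - ct$reference, margin = 2,
      comparison = sprintf("CT value %s - reference (HU)", nm))
  }
  study_report("dose_reduction", config, do.call(rbind, rows), stats_list)
}

#' Write a study report to disk
#'
#' Writes the per-replicate metric table, the per-condition summary, the
#' comparison results (CSV and JSON) and a human-readable summary including
#' the provenance hash. Identical config and seed produce byte-identical
#' files.
#'
#' @param report a `study_report`.
#' @param path output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "study_report")) stop("not a study_report")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path)
  paths <- file.path(path, c("metrics.csv", "summary.csv", "stats.csv",
                             "stats.json", "summary.txt"))
  utils::write.csv(report$metrics, paths[1], row.names = FALSE)
  utils::write.csv(report$summary, paths[2], row.names = FALSE)
  st <- stat_results_table(report$stats)
  utils::write.csv(st, paths[3], row.names = FALSE)
  jsonlite::write_json(st, paths[4], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  con <- file(paths[5], "w")
  on.exit(close(con))
  writeLines(sprintf("%s study | %d replicates | seed %d | config hash %s | legatoCT %s",
                     report$study, report$config$n_replicates,
                     report$config$seed, report$provenance$config_hash,
                     report$provenance$version), con)
  writeLines("", con)
  writeLines(utils::capture.output(print(report)), con)
  invisible(paths)
}
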