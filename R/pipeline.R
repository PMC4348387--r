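# End-to-end orchestration: synchronize, bin, fit, threshold, and summarize
# into a compliance result; plus the disk-level stages behind the command
# line interface.

#' Run the compliance pipeline on in-memory objects
#'
#' Full analysis chain: optional motion-correction hook (identity by
#' default), systolic peak detection on the plethysmograph trace, the
#' peripheral-delay shift, cardiac-phase assignment and binning, voxel-wise
#' kinetic fitting of the requested phase bins within the large-artery mask
#' (the per-slice 95th-percentile threshold of the mean difference image at
#' the ROI TI), the compliance map from the diastolic and systolic aBV maps,
#' and flow-territory medians.
#'
#' @param series An [asl_series()].
#' @param physio A [physio_trace()].
#' @param bp A [blood_pressures()] object.
#' @param broad_labels Integer 3D array of broad territory masks.
#' @param label_names Named integer vector mapping territory names to label
#'   values.
#' @param calib Optional calibration image for [calibrate_m0a()]; requires
#'   `csf_mask`.
#' @param csf_mask Logical array, CSF region of the calibration image.
#' @param mode Phase assignment mode, `"slice"` or `"label"`.
#' @param n_bins Number of cardiac-phase bins.
#' @param finger_delay Peripheral pulse delay (ms) removed from the trace.
#' @param roi_ti TI (ms) whose full-series mean difference image defines the
#'   artery mask.
#' @param percentile Per-slice intensity percentile for the mask.
#' @param dia_bin,sys_bin 1-based bins taken as early diastole and early
#'   systole (defaults: bin 2 = \[1/8, 2/8), bin 7 = \[6/8, 7/8)).
#' @param bins Bins to fit; defaults to all `n_bins` (the diastolic and
#'   systolic bins are always included).
#' @param cfg Optional [fit_config()]; built from the calibrated `m0a` when
#'   omitted.
#' @param summary_slice Optional slice index for territory medians (the
#'   slice just above the circle of Willis); `NULL` summarizes all slices.
#' @param csf_factor CSF-to-blood conversion for [calibrate_m0a()].
#' @param motion_correct Hook applied to `series` before analysis; the
#'   default is the identity (no registration is implemented).
#' @return An object of class `compliance_result`: `ac_map`, `abv_dia_map`,
#'   `abv_sys_map`, `param_maps` ([fit_maps()] output), `rois`, `mask`,
#'   `territory` (tidy data.frame of medians per territory and parameter),
#'   `balance` ([balance_report()]), `bp`, `m0a`.
#' @export
run_pipeline <- function(series, physio, bp, broad_labels,
                         label_names = NULL,
                         calib = NULL, csf_mask = NULL,
                         mode = c("slice", "label"), n_bins = 8,
                         finger_delay = 225, roi_ti = 750, percentile = 95,
                         dia_bin = 2, sys_bin = 7, bins = NULL,
                         cfg = NULL, summary_slice = NULL,
                         csf_factor = 0.87,
                         motion_correct = identity) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "asl_series"), inherits(bp, "blood_pressures"))
  series <- motion_correct(series)
  peaks <- detect_systolic_peaks(physio)
  shifted <- shift_peaks(peaks, finger_delay)
  assign <- assign_phases(series, shifted, mode = mode, n_bins = n_bins)
  binned <- phase_binned_delta(series, assign)
  balance <- balance_report(binned)
  mean_dm <- mean_delta_m(series, roi_ti)
  mask <- percentile_mask(mean_dm, percentile)
  rois <- territory_rois(mask, broad_labels, label_names)
  m0a <- if (!is.null(calib)) {
    if (is.null(csf_mask)) stop("calibration image given without a CSF mask")
    calibrate_m0a(calib, csf_mask, csf_factor)
  } else if (!is.null(cfg)) cfg$m0a else 1
  if (is.null(cfg)) cfg <- fit_config(m0a = m0a)
  if (is.null(bins)) bins <- seq_len(n_bins)
  bins <- sort(unique(c(bins, dia_bin, sys_bin)))
  pm <- fit_maps(binned, cfg, mask = mask, bins = bins)
  abv_dia <- pm$maps[[paste0("bin", dia_bin)]]$abv
  abv_sys <- pm$maps[[paste0("bin", sys_bin)]]$abv
  ac <- compliance_map(abv_dia, abv_sys, bp)
  terr <- rbind(
    cbind(parameter = "ac", territory_summary(ac, rois, summary_slice)),
    cbind(parameter = "abv_dia",
          territory_summary(abv_dia, rois, summary_slice)),
    cbind(parameter = "abv_sys",
          territory_summary(abv_sys, rois, summary_slice)))
  structure(list(ac_map = ac, abv_dia_map = abv_dia, abv_sys_map = abv_sys,
                 param_maps = pm, rois = rois, mask = mask,
                 territory = terr, balance = balance, bp = bp, m0a = m0a),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf("compliance_result (PP = %.1f mm Hg, m0a = %.4g)\n",
              x$bp$pp, x$m0a))
  ac <- x$territory[x$territory$parameter == "ac", ]
  for (i in seq_len(nrow(ac)))
    cat(sprintf("  %-6s AC = %6.3f %%/mmHg  (n = %d voxels)\n",
                ac$territory[i], ac$value[i], ac$n_voxels[i]))
  invisible(x)
}

#' Mean difference image of one TI's full series
#'
#' Mean of all control volumes minus mean of all tag volumes for the series
#' acquired at `ti`, ignoring cardiac phase; the basis of the artery mask.
#'
#' @param series An [asl_series()].
#' @param ti Inversion time (ms); must be present in the series.
#' @return 3D array.
#' @export
mean_delta_m <- function(series, ti) {
  i <- which(series$ti == ti)
  if (length(i) != 1) stop("TI ", ti, " ms not present in the series")
  dat <- series$data[[i]]
  lab <- series$label_order[[i]]
  mt <- rowMeans(dat[, , , lab == "tag", drop = FALSE], dims = 3)
  mc <- rowMeans(dat[, , , lab == "control", drop = FALSE], dims = 3)
  mc - mt
}

# --- disk-level stages behind the CLI ------------------------------------

#' Simulate a dataset to disk
#'
#' Builds the phantom and timing from the config (sections `phantom` and
#' `timing` hold [phantom_spec()] / [asl_timing()] arguments), simulates the
#' acquisition, writes the dataset and a manifest.
#'
#' @param cfg A validated pipeline config, see [read_pipeline_config()].
#' @param config_path Optional YAML path recorded in the manifest.
#' @return Output directory, invisibly.
#' @export
pipeline_simulate <- function(cfg, config_path = NULL) {
  cfg <- validate_pipeline_config(unclass(cfg))
  spec <- do.call(phantom_spec, cfg$phantom %||% list())
  timing <- do.call(asl_timing, cfg$timing %||% list())
  sim <- simulate_acquisition(spec, timing, seed = cfg$seed)
  write_asl_dataset(sim, cfg$output_dir)
  write_manifest(cfg$output_dir, cfg$seed, config_path)
  message("pipeline_simulate: dataset written to ", cfg$output_dir)
  invisible(cfg$output_dir)
}

#' Run the full pipeline from a dataset on disk
#'
#' Reads a dataset written by [pipeline_simulate()] (or arranged in the same
#' layout), runs [run_pipeline()], and writes per-bin parameter maps
#' (`maps_bin<k>_<param>.nii.gz`), the AC map, a tidy territory CSV, the
#' balance report TSV, and a manifest into `cfg$output_dir`.
#'
#' @inheritParams pipeline_simulate
#' @param input_dir Dataset directory; defaults to `cfg$input_dir`.
#' @return The [run_pipeline()] result, invisibly.
#' @export
pipeline_run <- function(cfg, input_dir = NULL, config_path = NULL) {
  cfg <- validate_pipeline_config(unclass(cfg))
  if (is.null(input_dir)) input_dir <- cfg$input_dir
  if (is.null(input_dir)) stop("stage 'read': no input_dir configured")
  ds <- tryCatch(read_asl_dataset(input_dir),
                 error = function(e) stop("stage 'read' failed: ",
                                          conditionMessage(e)))
  bp <- if (!is.null(cfg$bp)) blood_pressures(cfg$bp$sys, cfg$bp$dia)
        else ds$bp
  res <- tryCatch(
    run_pipeline(ds$series, ds$physio, bp, ds$labels,
                 label_names = ds$label_names,
                 calib = ds$calib, csf_mask = ds$csf_mask,
                 mode = cfg$mode, n_bins = cfg$n_bins,
                 finger_delay = cfg$finger_delay,
                 roi_ti = cfg$roi_ti %||% 750,
                 percentile = cfg$percentile,
                 dia_bin = cfg$dia_bin, sys_bin = cfg$sys_bin,
                 bins = cfg$bins, summary_slice = cfg$summary_slice,
                 csf_factor = cfg$csf_factor),
    error = function(e) stop("stage 'analysis' failed: ",
                             conditionMessage(e)))
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  for (bn in names(res$param_maps$maps)) {
    for (pn in c("abv", "dt", "sigma", "rmse")) {
      RNifti::writeNifti(RNifti::asNifti(res$param_maps$maps[[bn]][[pn]]),
                         file.path(out, sprintf("maps_%s_%s.nii.gz", bn, pn)))
    }
  }
  RNifti::writeNifti(RNifti::asNifti(res$ac_map),
                     file.path(out, "ac_map.nii.gz"))
  utils::write.csv(res$territory, file.path(out, "territory_summary.csv"),
                   row.names = FALSE)
  utils::write.table(res$balance, file.path(out, "balance_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(out, cfg$seed, config_path)
  message("pipeline_run: outputs written to ", out)
  invisible(res)
}

#' Run the contamination study to CSV
#'
#' Wraps [simulation_study()]; the config section `study` holds its
#' arguments (`abv_grid`, `dt_tiss_list`, `cbf`, `dt_art`, `sigma_true`).
#'
#' @inheritParams pipeline_simulate
#' @return The study data.frame, invisibly; written to
#'   `<output_dir>/contamination_study.csv`.
#' @export
pipeline_study <- function(cfg, config_path = NULL) {
  cfg <- validate_pipeline_config(unclass(cfg))
  args <- cfg$study %||% list()
  if (is.null(args$abv_grid)) args$abv_grid <- seq(0.5, 10, by = 0.5)
  tab <- do.call(simulation_study, args)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(tab, file.path(out, "contamination_study.csv"),
                   row.names = FALSE)
  write_manifest(out, cfg$seed, config_path)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
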