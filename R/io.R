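# Readers and writers: NIfTI image series with JSON sidecars, TSV physio
# traces, YAML pipeline configuration, run manifests, and the bundled
# printed reference tables.

#' Write a simulated dataset to disk
#'
#' Emits the formats the pipeline reads: one 4D NIfTI per TI with a JSON
#' sidecar (TI, tag/control order, labeling times, timing constants), the
#' physio trace as two-column TSV (time_ms, amplitude) with a JSON sidecar
#' (fs, t0), the calibration image, the territory label map with a label
#' dictionary, and the ground truth as a TSV keyed by territory.
#'
#' @param sim An [simulate_acquisition()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_asl_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "asl_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ser <- sim$series
  for (i in seq_along(ser$ti)) {
    stem <- file.path(dir, sprintf("asl_ti%04d", ser$ti[i]))
    RNifti::writeNifti(RNifti::asNifti(ser$data[[i]]),
                       paste0(stem, ".nii.gz"))
    jsonlite::write_json(
      list(ti = ser$ti[i], label_order = ser$label_order[[i]],
           vol_times = ser$vol_times[[i]], slice_delay = ser$slice_delay,
           tr = ser$tr),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  write_physio_tsv(sim$physio, file.path(dir, "physio.tsv"))
  RNifti::writeNifti(RNifti::asNifti(sim$calib),
                     file.path(dir, "calib.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(sim$truth$labels + 0),
                     file.path(dir, "territories.nii.gz"))
  jsonlite::write_json(
    as.list(stats::setNames(sim$spec$territories$label,
                            sim$spec$territories$name)),
    file.path(dir, "territories.json"), auto_unbox = TRUE)
  RNifti::writeNifti(RNifti::asNifti(sim$truth$csf_mask + 0),
                     file.path(dir, "csf_mask.nii.gz"))
  jsonlite::write_json(list(bp_sys = sim$spec$bp_sys,
                            bp_dia = sim$spec$bp_dia),
                       file.path(dir, "bp.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(sim$spec$territories, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_asl_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list: `series` ([asl_series()]), `physio` ([physio_trace()]),
#'   `calib`, `labels`, `label_names`, `csf_mask`, `bp`
#'   ([blood_pressures()]).
#' @export
read_asl_dataset <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^asl_ti[0-9]+\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0) stop("no ASL series found in ", dir)
  data <- list(); ti <- numeric(); lab <- list(); vt <- list()
  slice_delay <- NA; tr <- NA
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    img <- RNifti::readNifti(sub("\\.json$", ".nii.gz", sc))
    data[[length(data) + 1]] <- array(as.numeric(img), dim(img))
    ti <- c(ti, meta$ti)
    lab[[length(lab) + 1]] <- meta$label_order
    vt[[length(vt) + 1]] <- meta$vol_times
    slice_delay <- meta$slice_delay
    tr <- meta$tr
  }
  # restore acquisition order (labeling times increase over the session)
  ord <- order(vapply(vt, function(x) x[1], numeric(1)))
  series <- asl_series(data[ord], ti[ord], lab[ord], vt[ord],
                       slice_delay, tr)
  physio <- read_physio_tsv(file.path(dir, "physio.tsv"))
  calib_img <- RNifti::readNifti(file.path(dir, "calib.nii.gz"))
  lab_img <- RNifti::readNifti(file.path(dir, "territories.nii.gz"))
  lab_dict <- jsonlite::read_json(file.path(dir, "territories.json"),
                                  simplifyVector = TRUE)
  csf_img <- RNifti::readNifti(file.path(dir, "csf_mask.nii.gz"))
  bp <- jsonlite::read_json(file.path(dir, "bp.json"), simplifyVector = TRUE)
  list(series = series,
       physio = physio,
       calib = array(as.numeric(calib_img), dim(calib_img)),
       labels = array(as.integer(round(lab_img)), dim(lab_img)),
       label_names = stats::setNames(as.integer(unlist(lab_dict)),
                                     names(lab_dict)),
       csf_mask = array(as.numeric(csf_img) > 0.5, dim(csf_img)),
       bp = blood_pressures(bp$bp_sys, bp$bp_dia))
}

#' Write a physio trace as TSV with a JSON sidecar
#'
#' @param trace A [physio_trace()].
#' @param path TSV path (columns `time_ms`, `amplitude`); the sidecar
#'   `<path>.json` records `fs` and `t0`.
#' @return `path`, invisibly.
#' @export
write_physio_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  t <- trace$t0 + (seq_along(trace$samples) - 1) / trace$fs * 1000
  utils::write.table(data.frame(time_ms = t, amplitude = trace$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = trace$fs, t0 = trace$t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a physio trace from TSV
#'
#' Accepts either a two-column TSV (`time_ms`, `amplitude`) or a
#' single-column TSV with `fs`/`t0` in a `<path>.json` sidecar.
#'
#' @param path TSV path.
#' @return A [physio_trace()].
#' @export
read_physio_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".json")
  if ("time_ms" %in% names(tab)) {
    dt <- diff(tab$time_ms)
    fs <- 1000 / stats::median(dt)
    t0 <- tab$time_ms[1]
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      fs <- meta$fs
      t0 <- meta$t0
    }
    physio_trace(tab$amplitude, fs, t0)
  } else {
    if (!file.exists(side))
      stop("single-column physio TSV needs a JSON sidecar with fs and t0")
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    physio_trace(tab[[1]], meta$fs, meta$t0)
  }
}

#' Bundled subject reference table
#'
#' Per-subject brachial pressures, heart rate and the slice just above the
#' circle of Willis for the five-subject reference protocol, as published.
#'
#' @param path Override the bundled TSV.
#' @return data.frame with columns `subject`, `age`, `sex`, `bp_sys`,
#'   `bp_dia`, `pp`, `heart_rate_bpm`, `slice_above_cow`.
#' @export
read_subject_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subjects.tsv", package = "aslcompliance",
                        mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Bundled group compliance table
#'
#' Published group-average compliance per flow territory (%/mm Hg), used as
#' example input for cycle-change arithmetic.
#'
#' @param path Override the bundled TSV.
#' @return data.frame with columns `territory`, `ac_mean`, `ac_sd`.
#' @export
read_group_compliance <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "group_compliance.tsv",
                        package = "aslcompliance", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration covering the whole pipeline. All protocol constants
#' (225 ms finger delay, 8 bins, 95th percentile, 700 ms bolus duration,
#' 1664 ms blood T1, unit labeling efficiency) live here as defaults, never
#' as literals inside stage code.
#'
#' @param path YAML file path.
#' @return The validated config list (class `pipeline_config`), with
#'   defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A raw config list.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(seed = 1L, output_dir = "aslcompliance_out",
                   mode = "slice", n_bins = 8L, finger_delay = 225,
                   percentile = 95, tau = 700, alpha = 1, t1a = 1664,
                   dia_bin = 2L, sys_bin = 7L, csf_factor = 0.87,
                   summary_slice = NULL)
  problems <- character()
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$mode %in% c("slice", "label"))
    problems <- c(problems, "mode must be 'slice' or 'label'")
  num_pos <- c("n_bins", "percentile", "tau", "t1a")
  for (nm in num_pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      problems <- c(problems, sprintf("%s must be a positive number", nm))
  if (!is.numeric(cfg$finger_delay))
    problems <- c(problems, "finger_delay must be numeric")
  if (!is.null(cfg$bp) &&
      !(is.numeric(cfg$bp$sys) && is.numeric(cfg$bp$dia)))
    problems <- c(problems, "bp must hold numeric sys and dia readings")
  if (length(problems) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a run manifest
#'
#' Records package version, seed and the MD5 of the config file so a run
#' can be reproduced exactly.
#'
#' @param dir Output directory.
#' @param seed Seed used for the run.
#' @param config_path Optional path of the YAML config that drove the run.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, config_path = NULL) {
  man <- list(package = "aslcompliance",
              version = as.character(utils::packageVersion("aslcompliance")),
              seed = seed,
              config_md5 = if (!is.null(config_path))
                unname(tools::md5sum(config_path)) else NA)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
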