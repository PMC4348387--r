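# Data containers shared across the pipeline.

#' Plethysmograph trace
#'
#' A uniformly sampled peripheral pulse waveform on the same clock as the
#' image acquisition timestamps.
#'
#' @param samples Numeric waveform amplitudes (arbitrary units), non-empty.
#' @param fs Sampling rate in Hz, positive.
#' @param t0 Time of the first sample (ms).
#' @return An object of class `physio_trace`.
#' @export
physio_trace <- function(samples, fs, t0 = 0) {
  stopifnot(length(samples) > 0, is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("physio_trace: %d samples @ %g Hz, t0 = %g ms (%.1f s)\n",
              length(x$samples), x$fs, x$t0,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Acquisition timing metadata
#'
#' Protocol timing for a multi-TI PASL acquisition: each inversion time is
#' acquired as a separate series of alternating tag/control volumes
#' (tag first), volumes spaced by `tr`, ascending slices spaced by
#' `slice_delay` within each volume, and series separated by `series_gap`.
#' The default values are the intended scanner protocol (TR 1400 ms, seven
#' TIs 250-850 ms, 80 tag-control pairs per TI, 14 slices, 29 ms slice
#' delay, QUIPSS II cut-off 700 ms).
#'
#' @param tr Repetition time (ms); must exceed the largest TI.
#' @param ti_list Inversion times (ms), strictly increasing.
#' @param n_pairs Tag-control pairs per TI.
#' @param n_slices Number of slices per volume.
#' @param slice_delay Per-slice acquisition delay (ms).
#' @param quipss_cutoff QUIPSS II bolus cut-off (ms); the fitted bolus
#'   duration.
#' @param series_gap Dead time between consecutive TI series (ms).
#' @param t0 Labeling time of the first volume of the first series (ms).
#' @return An object of class `asl_timing`.
#' @export
asl_timing <- function(tr = 1400, ti_list = seq(250, 850, by = 100),
                       n_pairs = 80, n_slices = 14, slice_delay = 29,
                       quipss_cutoff = 700, series_gap = 5000, t0 = 5000) {
  stopifnot(tr > max(ti_list), all(diff(ti_list) > 0), slice_delay >= 0,
            n_pairs >= 1, n_slices >= 1, series_gap >= 0)
  structure(list(tr = tr, ti_list = ti_list, n_pairs = n_pairs,
                 n_slices = n_slices, slice_delay = slice_delay,
                 quipss_cutoff = quipss_cutoff, series_gap = series_gap,
                 t0 = t0),
            class = "asl_timing")
}

#' Multi-TI PASL tag/control series
#'
#' Container for one session of multi-TI PASL data: per TI, a 4D array of
#' volumes (x, y, z, volume), the tag/control label of each volume, and the
#' labeling time of each volume on the physio clock. Tag/control identity
#' always comes from this metadata, never from image intensities.
#'
#' @param data List of 4D numeric arrays, one per TI.
#' @param ti Inversion time of each element of `data` (ms).
#' @param label_order List of character vectors (`"tag"`/`"control"`) per TI,
#'   length matching the 4th dimension of the corresponding array.
#' @param vol_times List of numeric vectors: labeling time of each volume
#'   (ms).
#' @param slice_delay Per-slice acquisition delay (ms).
#' @param tr Repetition time (ms).
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(data, ti, label_order, vol_times, slice_delay, tr) {
  stopifnot(is.list(data), length(data) == length(ti),
            length(label_order) == length(ti),
            length(vol_times) == length(ti))
  for (i in seq_along(data)) {
    stopifnot(length(dim(data[[i]])) == 4,
              dim(data[[i]])[4] == length(label_order[[i]]),
              dim(data[[i]])[4] == length(vol_times[[i]]),
              all(label_order[[i]] %in% c("tag", "control")))
  }
  structure(list(data = data, ti = ti, label_order = label_order,
                 vol_times = vol_times, slice_delay = slice_delay, tr = tr),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("asl_series: %d TIs (%s ms), grid %dx%dx%d, %d volumes/TI\n",
              length(x$ti), paste(x$ti, collapse = ", "),
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
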