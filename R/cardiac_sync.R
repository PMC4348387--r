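# Retrospective cardiac synchronization: systolic peak detection on the
# plethysmograph trace, normalized cardiac phase of every (volume, slice),
# phase binning, and assembly of phase-binned difference images with
# tag/control balance accounting.

#' Detect systolic peaks in a plethysmograph trace
#'
#' Band-passes the trace (Butterworth, zero-phase) and keeps local maxima
#' above an amplitude threshold, enforcing a refractory period so each
#' heartbeat contributes a single peak.
#'
#' @param trace A [physio_trace()].
#' @param band Pass band in Hz; the upper edge is clamped below Nyquist.
#' @param refractory Minimum spacing between retained peaks (ms).
#' @param rr_bounds Physiological inter-peak interval bounds (ms); intervals
#'   outside produce a warning.
#' @return Numeric vector of strictly increasing peak times (ms), with the
#'   out-of-bounds interval count in attribute `"n_flagged"`.
#' @export
detect_systolic_peaks <- function(trace, band = c(0.5, 8),
                                  refractory = 250,
                                  rr_bounds = c(250, 2000)) {
  stopifnot(inherits(trace, "physio_trace"))
  x <- trace$samples
  if (length(x) < 8 || stats::sd(x) == 0)
    stop("unusable physio trace: flat or too short")
  hi <- min(band[2], 0.45 * trace$fs)
  bf <- signal::butter(2, c(band[1], hi) / (trace$fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  thr <- 0.4 * stats::quantile(xf[xf > 0], 0.98, names = FALSE)
  n <- length(xf)
  cand <- which(xf > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[xf[cand] >= xf[cand - 1] & xf[cand] >= xf[cand + 1]]
  if (length(cand) == 0) stop("unusable physio trace: no peaks detected")
  # refractory pass: within the dead time keep the taller peak
  gap <- refractory * trace$fs / 1000
  kept <- cand[1]
  for (i in cand[-1]) {
    last <- kept[length(kept)]
    if (i - last >= gap) kept <- c(kept, i)
    else if (xf[i] > xf[last]) kept[length(kept)] <- i
  }
  if (length(kept) < 2) stop("unusable physio trace: fewer than 2 beats")
  # refine each peak on the raw trace (the band-pass can skew asymmetric
  # pulse shapes by a few samples)
  half <- round(0.4 * gap)
  kept <- vapply(kept, function(i) {
    w <- max(1, i - half):min(n, i + half)
    w[which.max(x[w])]
  }, integer(1))
  kept <- sort(unique(kept))
  peaks <- trace$t0 + (kept - 1) / trace$fs * 1000
  rr <- diff(peaks)
  n_flag <- sum(rr < rr_bounds[1] | rr > rr_bounds[2])
  if (n_flag > 0)
    warning(sprintf("%d inter-peak interval(s) outside %g-%g ms",
                    n_flag, rr_bounds[1], rr_bounds[2]))
  attr(peaks, "n_flagged") <- n_flag
  peaks
}

#' Shift peak times for the peripheral pulse delay
#'
#' The finger pulse lags the cerebral pulse; subtracting the transit delay
#' (225 ms by default) aligns the plethysmograph peaks with the cardiac
#' events seen by the cerebral arteries.
#'
#' @param peaks Peak times (ms).
#' @param delay Transit delay (ms), non-negative by convention but any value
#'   is accepted so the shift is invertible.
#' @return Shifted peak times, `peaks - delay`.
#' @export
shift_peaks <- function(peaks, delay = 225) {
  as.numeric(peaks) - delay
}

#' Normalized cardiac phase of an acquisition time
#'
#' Phase advances linearly from 0 at one systolic peak to 1 at the next and
#' resets: `phi = (t_acq - t1)/(t2 - t1)` with `t1 <= t_acq < t2` the
#' bracketing peaks.
#'
#' @param t_acq Acquisition times (ms); vectorized.
#' @param peaks Strictly increasing (shifted) peak times (ms).
#' @param on_outside `"error"` to stop when a time falls outside the peak
#'   range, `"na"` to return `NA` for it (callers then drop the volume).
#' @return Phases in \[0, 1).
#' @export
cardiac_phase <- function(t_acq, peaks, on_outside = c("error", "na")) {
  on_outside <- match.arg(on_outside)
  stopifnot(length(peaks) >= 2, all(diff(peaks) > 0))
  idx <- findInterval(t_acq, peaks)
  out <- idx < 1 | idx >= length(peaks)
  if (any(out)) {
    if (on_outside == "error")
      stop("acquisition time outside the physio trace peak range")
    idx[out] <- NA_integer_
  }
  phi <- (t_acq - peaks[idx]) / (peaks[idx + 1] - peaks[idx])
  phi[!is.na(phi) & phi >= 1] <- 0  # t_acq exactly on a peak boundary
  phi
}

# bin index in 1..n_bins for phi in [0,1); bin k covers [(k-1)/n, k/n)
phase_bin <- function(phi, n_bins = 8) {
  b <- floor(n_bins * phi) + 1L
  b[b > n_bins] <- n_bins  # guard against phi numerically equal to 1
  b
}

#' Assign cardiac phases to every (volume, slice)
#'
#' In `"slice"` mode the phase of slice `s` of a volume is taken at its
#' acquisition time `t_label + TI + (s-1) * slice_delay`; in `"label"` mode
#' every slice inherits the phase of the labeling time, so a phase bin then
#' collects slices labeled at a fixed point of the cardiac cycle. Volumes
#' whose times fall outside the physio trace are dropped with a message,
#' not an error.
#'
#' @param series An [asl_series()].
#' @param peaks Shifted systolic peak times (ms), see [shift_peaks()].
#' @param mode `"slice"` (default) or `"label"`.
#' @param n_bins Number of phase bins partitioning \[0, 1) into half-open
#'   intervals.
#' @return An object of class `phase_assignment`: per TI, matrices `phi`,
#'   `bin` and logical `keep` of dimension (volumes x slices).
#' @export
assign_phases <- function(series, peaks, mode = c("slice", "label"),
                          n_bins = 8) {
  stopifnot(inherits(series, "asl_series"))
  mode <- match.arg(mode)
  per_ti <- vector("list", length(series$ti))
  n_dropped <- 0L
  for (i in seq_along(series$ti)) {
    tl <- series$vol_times[[i]]
    ns <- dim(series$data[[i]])[3]
    t_acq <- if (mode == "slice") {
      outer(tl + series$ti[i], (seq_len(ns) - 1) * series$slice_delay, `+`)
    } else {
      matrix(tl, nrow = length(tl), ncol = ns)
    }
    phi <- matrix(cardiac_phase(as.numeric(t_acq), peaks, on_outside = "na"),
                  nrow = length(tl))
    keep <- !is.na(phi)
    n_dropped <- n_dropped + sum(!keep)
    bin <- matrix(NA_integer_, nrow = nrow(phi), ncol = ncol(phi))
    bin[keep] <- phase_bin(phi[keep], n_bins)
    per_ti[[i]] <- list(phi = phi, bin = bin, keep = keep)
  }
  if (n_dropped > 0)
    message(sprintf("assign_phases: dropped %d slice acquisitions outside the physio trace",
                    n_dropped))
  structure(list(per_ti = per_ti, ti = series$ti, mode = mode,
                 n_bins = n_bins, n_dropped = n_dropped),
            class = "phase_assignment")
}

#' Phase-binned difference images
#'
#' For every (TI, phase bin, slice): the mean control image minus the mean
#' tag image over the volumes whose slice fell in that bin, with tag and
#' control counts recorded. Cells with no tag or no control contribution
#' hold `NA` rather than raising an error.
#'
#' @param series An [asl_series()].
#' @param assign A [assign_phases()] result for the same series.
#' @return An object of class `phase_binned_delta`: per TI a 4D array
#'   `delta_m` (x, y, z, bin) and count matrices `n_tag`, `n_control`
#'   (bin x slice).
#' @export
phase_binned_delta <- function(series, assign) {
  stopifnot(inherits(series, "asl_series"),
            inherits(assign, "phase_assignment"),
            length(series$ti) == length(assign$per_ti))
  nb <- assign$n_bins
  out <- vector("list", length(series$ti))
  for (i in seq_along(series$ti)) {
    dat <- series$data[[i]]
    d <- dim(dat)
    lab <- series$label_order[[i]]
    bin <- assign$per_ti[[i]]$bin
    dm <- array(NA_real_, c(d[1], d[2], d[3], nb))
    n_tag <- matrix(0L, nb, d[3])
    n_ctl <- matrix(0L, nb, d[3])
    for (s in seq_len(d[3])) {
      for (b in seq_len(nb)) {
        vt <- which(bin[, s] == b & lab == "tag")
        vc <- which(bin[, s] == b & lab == "control")
        n_tag[b, s] <- length(vt)
        n_ctl[b, s] <- length(vc)
        if (length(vt) > 0 && length(vc) > 0) {
          mt <- if (length(vt) == 1) dat[, , s, vt]
                else rowMeans(dat[, , s, vt, drop = FALSE], dims = 2)
          mc <- if (length(vc) == 1) dat[, , s, vc]
                else rowMeans(dat[, , s, vc, drop = FALSE], dims = 2)
          dm[, , s, b] <- mc - mt
        }
      }
    }
    out[[i]] <- list(delta_m = dm, n_tag = n_tag, n_control = n_ctl)
  }
  structure(list(per_ti = out, ti = series$ti, n_bins = nb,
                 slice_delay = series$slice_delay),
            class = "phase_binned_delta")
}

#' Tag/control balance report
#'
#' Long-format table of tag and control counts per (TI, bin, slice), used to
#' check that retrospective synchronization did not bias any cardiac phase
#' or TI. Cells whose tag or control count falls below `floor` are flagged.
#'
#' @param binned A [phase_binned_delta()] result.
#' @param floor Minimum acceptable count per cell.
#' @return A data.frame with columns `ti`, `bin`, `slice`, `n_tag`,
#'   `n_control`, `flagged`.
#' @export
balance_report <- function(binned, floor = 3) {
  stopifnot(inherits(binned, "phase_binned_delta"))
  rows <- lapply(seq_along(binned$ti), function(i) {
    nt <- binned$per_ti[[i]]$n_tag
    nc <- binned$per_ti[[i]]$n_control
    expand <- expand.grid(bin = seq_len(nrow(nt)), slice = seq_len(ncol(nt)))
    data.frame(ti = binned$ti[i], expand,
               n_tag = as.integer(nt), n_control = as.integer(nc))
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$n_tag < floor | out$n_control < floor
  out
}

#' Cardiac-phase offset accumulated across a slice stack
#'
#' When images are sorted by the cardiac phase of the *label*, each later
#' slice of a volume is acquired deeper into the cardiac cycle; the offset
#' between the most proximal and most distal slice is
#' `n_slices * slice_delay / rr` cardiac-phase units.
#'
#' @param n_slices Number of slices.
#' @param slice_delay Per-slice delay (ms).
#' @param rr R-R interval (ms).
#' @return Phase offset in cardiac-phase units.
#' @export
slice_stack_phase_offset <- function(n_slices, slice_delay, rr) {
  n_slices * slice_delay / rr
}
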