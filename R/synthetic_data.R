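# Synthetic acquisition generator: cardiac-modulated multi-TI tag/control
# series over a digital phantom with territory-shaped arterial blobs and a
# tissue background, a matching plethysmograph trace with a peripheral
# delay, a calibration image, and the microvascular-contamination study.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Geometry and ground-truth physiology of the digital phantom: five
#' territory blobs (right/left middle, anterior, right/left posterior
#' cerebral artery territories) on the slices around the nominal circle of
#' Willis, a perfused tissue background, and a CSF region for calibration.
#' Default diastolic aBV values lie in the 1.5-2.5 %v range of large-artery
#' voxels; systolic arrival time exceeds diastolic by 41 ms and diastolic
#' dispersion exceeds systolic by 30 ms, matching the physiological pattern
#' the method is designed to detect. Systolic aBV is derived from the
#' planted per-territory compliance and the phantom's pulse pressure.
#'
#' @param dim Grid dimensions (x, y, z).
#' @param territories data.frame with columns `name`, `label`, `cx`, `cy`,
#'   `radius`, `abv_dia` (%v), `ac` (%/mm Hg), `dt_dia` (ms), `sigma_sys`
#'   (ms); `NULL` for the default five-territory layout.
#' @param territory_slices Slice indices carrying the territory blobs.
#' @param dt_sys_offset Systolic minus diastolic arrival time (ms).
#' @param sigma_dia_offset Diastolic minus systolic dispersion width (ms).
#' @param cbf Tissue perfusion of the background (mL/100 g/min).
#' @param dt_tiss Tissue arrival time (ms), absolute.
#' @param bp_sys,bp_dia Phantom brachial pressures (mm Hg).
#' @param hr_mean,hr_sd Heart rate mean and s.d. (bpm).
#' @param finger_delay Peripheral pulse transit delay (ms).
#' @param noise_sd Additive Gaussian noise s.d. on each image, as a fraction
#'   of `m0a`.
#' @param m0a Equilibrium magnetization of arterial blood (signal units).
#' @param csf_factor CSF-to-blood conversion factor embedded in the
#'   calibration image (see [calibrate_m0a()]).
#' @param seed Default seed used by [simulate_acquisition()].
#' @return An object of class `phantom_spec`. Territory columns `abv_sys`,
#'   `dt_sys`, `sigma_dia` are filled in from the offsets and compliance.
#' @export
phantom_spec <- function(dim = c(24, 24, 14),
                         territories = NULL,
                         territory_slices = 3:5,
                         dt_sys_offset = 41,
                         sigma_dia_offset = 30,
                         cbf = 60, dt_tiss = 800,
                         bp_sys = 115.5, bp_dia = 62.8,
                         hr_mean = 65, hr_sd = 3,
                         finger_delay = 225,
                         noise_sd = 0.001, m0a = 1,
                         csf_factor = 0.87, seed = 1L) {
  if (is.null(territories)) {
    territories <- data.frame(
      name = c("RMCA", "LMCA", "ACA", "RPCA", "LPCA"),
      label = 1:5,
      cx = c(6, 18, 12, 8, 16),
      cy = c(13, 13, 19, 6, 6),
      radius = 1.6,
      abv_dia = c(2.0, 2.2, 1.8, 1.6, 1.68),
      ac = c(0.57, 0.50, 0.43, 1.1, 1.1),
      dt_dia = c(430, 435, 460, 445, 445),
      sigma_sys = c(80, 85, 90, 85, 85))
  }
  stopifnot(all(c("name", "label", "cx", "cy", "radius", "abv_dia", "ac",
                  "dt_dia", "sigma_sys") %in% names(territories)))
  if (!all(territories$cx >= 1 & territories$cx <= dim[1] &
             territories$cy >= 1 & territories$cy <= dim[2]))
    stop("territory centers fall outside the phantom grid; ",
         "supply a territories table matching `dim`")
  stopifnot(all(territory_slices >= 1), all(territory_slices <= dim[3]))
  pp <- bp_sys - bp_dia
  stopifnot(pp > 0, hr_mean > 30, hr_mean < 200, noise_sd >= 0)
  territories$abv_sys <- territories$abv_dia * (1 + territories$ac * pp / 100)
  territories$dt_sys <- territories$dt_dia + dt_sys_offset
  territories$sigma_dia <- territories$sigma_sys + sigma_dia_offset
  stopifnot(all(territories$abv_sys >= territories$abv_dia))
  structure(list(dim = dim, territories = territories,
                 territory_slices = territory_slices,
                 cbf = cbf, dt_tiss = dt_tiss,
                 bp_sys = bp_sys, bp_dia = bp_dia,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 finger_delay = finger_delay, noise_sd = noise_sd,
                 m0a = m0a, csf_factor = csf_factor, seed = seed),
            class = "phantom_spec")
}

# phantom geometry: territory label map, brain (tissue) mask, CSF blob
phantom_geometry <- function(spec) {
  d <- spec$dim
  labels <- array(0L, d)
  xg <- matrix(rep(seq_len(d[1]), d[2]), d[1])
  yg <- matrix(rep(seq_len(d[2]), each = d[1]), d[1])
  for (k in seq_len(nrow(spec$territories))) {
    tr <- spec$territories[k, ]
    disc <- (xg - tr$cx)^2 + (yg - tr$cy)^2 <= tr$radius^2
    for (z in spec$territory_slices) {
      sl <- labels[, , z]
      sl[disc] <- tr$label
      labels[, , z] <- sl
    }
  }
  # elliptical brain mask on every slice
  brain <- array(FALSE, d)
  ell <- ((xg - (d[1] + 1) / 2) / (0.45 * d[1]))^2 +
    ((yg - (d[2] + 1) / 2) / (0.45 * d[2]))^2 <= 1
  for (z in seq_len(d[3])) brain[, , z] <- ell
  # small central CSF blob on the middle slices
  csf <- array(FALSE, d)
  blob <- (xg - (d[1] + 1) / 2)^2 + (yg - (d[2] + 1) / 2)^2 <= 2.5^2
  for (z in intersect(seq_len(d[3]), spec$territory_slices + 4)) {
    csf[, , z] <- blob
  }
  if (!any(csf)) csf[, , d[3]] <- blob
  tissue <- brain & labels == 0L & !csf
  list(labels = labels, brain = brain, tissue = tissue, csf = csf)
}

#' Generate a plethysmograph trace with known beat times
#'
#' Quasi-periodic pulse waveform: beat-to-beat intervals are i.i.d. normal
#' around `60000/hr_mean`, each beat contributes a raised-cosine systolic
#' upstroke followed by an exponential decay, and the waveform peaks lag the
#' true cardiac events by the peripheral transit delay.
#'
#' @param hr_mean Mean heart rate (bpm), in (30, 200).
#' @param hr_sd Heart-rate s.d. (bpm); 0 gives an exactly periodic trace.
#' @param duration Trace duration (ms).
#' @param fs Sampling rate (Hz).
#' @param finger_delay Peripheral transit delay (ms).
#' @param seed Optional seed (caller RNG is restored afterwards).
#' @param t0 Trace start time (ms). Beats are laid down from `t0` onward.
#' @return A list: `trace` ([physio_trace()]), `beat_times` (true cardiac
#'   events, ms), `peak_times` (waveform peaks, `beat_times + finger_delay`).
#' @export
generate_physio <- function(hr_mean, hr_sd, duration, fs = 50,
                            finger_delay = 225, seed = NULL, t0 = 0) {
  stopifnot(hr_mean > 30, hr_mean < 200, hr_sd >= 0, duration > 0, fs > 0)
  with_seed(seed, {
    rr_mean <- 60000 / hr_mean
    rr_sd <- rr_mean * hr_sd / hr_mean
    n_max <- ceiling(duration / rr_mean * 1.5) + 10
    rr <- stats::rnorm(n_max, rr_mean, rr_sd)
    rr <- pmax(rr, 0.4 * rr_mean)  # guard against non-physiological draws
    beats <- t0 + c(0, cumsum(rr))
    beats <- beats[beats <= t0 + duration]
    peaks <- beats + finger_delay
    ts <- t0 + seq(0, duration, by = 1000 / fs)
    amp <- numeric(length(ts))
    up <- 100    # upstroke duration (ms)
    dec <- 300   # decay time constant (ms)
    for (q in peaks) {
      w <- which(ts >= q - up & ts <= q + 1200)
      r <- ts[w] - q
      a <- ifelse(r <= 0, 0.5 * (1 + cos(pi * r / up)), exp(-r / dec))
      amp[w] <- amp[w] + a
    }
    list(trace = physio_trace(amp, fs, t0 = t0),
         beat_times = beats, peak_times = peaks)
  })
}

#' Ground-truth arterial parameters at a cardiac phase
#'
#' Smooth periodic interpolation of each territory's arterial parameters
#' between their diastolic values (anchored at the center of the early
#' diastole bin, phase 1.5/8) and systolic values (center of the early
#' systole bin, phase 6.5/8), using a piecewise raised-cosine weight that is
#' continuous and periodic in phase with zero slope at both anchors.
#'
#' @param spec A [phantom_spec()].
#' @param phi Cardiac phase in \[0, 1); scalar.
#' @return data.frame with one row per territory: `name`, `label`, `abv`
#'   (%v), `dt` (ms), `sigma` (ms).
#' @export
phase_modulated_params <- function(spec, phi) {
  stopifnot(inherits(spec, "phantom_spec"), phi >= 0, phi < 1)
  g <- systolic_weight(phi)
  tr <- spec$territories
  data.frame(name = tr$name, label = tr$label,
             abv = tr$abv_dia + g * (tr$abv_sys - tr$abv_dia),
             dt = tr$dt_dia + g * (tr$dt_sys - tr$dt_dia),
             sigma = tr$sigma_dia + g * (tr$sigma_sys - tr$sigma_dia))
}

# raised-cosine weight: 0 at the diastolic anchor (phase 1.5/8), 1 at the
# systolic anchor (phase 6.5/8), C1-continuous and periodic
systolic_weight <- function(phi) {
  phi_dia <- 1.5 / 8
  phi_sys <- 6.5 / 8
  l1 <- phi_sys - phi_dia        # forward arc dia -> sys
  l2 <- 1 - l1                   # return arc sys -> dia
  u <- (phi - phi_dia) %% 1
  ifelse(u <= l1,
         0.5 * (1 - cos(pi * u / l1)),
         0.5 * (1 + cos(pi * (u - l1) / l2)))
}

#' Simulate a full multi-TI acquisition
#'
#' Generates, with known ground truth, everything the pipeline consumes: a
#' plethysmograph trace, one tag/control series per inversion time (TIs
#' acquired in randomized order, volumes alternating tag first), a
#' calibration image with a CSF region, the territory label map, and the
#' phantom's blood pressures. Each slice's difference signal is the
#' two-compartment model evaluated at its effective inversion time with
#' arterial parameters taken at the slice's true cardiac phase; controls
#' carry the static baseline, tags carry baseline minus the difference
#' signal, and independent Gaussian noise is added to both.
#'
#' @param spec A [phantom_spec()].
#' @param timing An [asl_timing()].
#' @param seed Seed controlling beat times, TI order and noise; defaults to
#'   `spec$seed`. Identical seeds give identical outputs.
#' @param fs Plethysmograph sampling rate (Hz); the phase resolution of the
#'   retrospective synchronization is limited by `1000/fs` ms.
#' @return An object of class `asl_simulation`: `series` ([asl_series()]),
#'   `physio` ([physio_trace()]), `calib` (3D array), `bp`
#'   ([blood_pressures()]), `timing`, `spec`, and `truth` (beat/peak times,
#'   label map, tissue and CSF masks, and per-TI matrices of the true phase
#'   of every (volume, slice)).
#' @export
simulate_acquisition <- function(spec, timing, seed = spec$seed, fs = 100) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(timing, "asl_timing"))
  with_seed(seed, {
    geo <- phantom_geometry(spec)
    d <- spec$dim
    n_vol <- 2L * timing$n_pairs
    ti_order <- sample(timing$ti_list)
    series_len <- n_vol * timing$tr
    starts <- timing$t0 +
      (seq_along(ti_order) - 1) * (series_len + timing$series_gap)
    end_time <- starts[length(starts)] + series_len +
      max(timing$ti_list) + timing$n_slices * timing$slice_delay
    phys <- generate_physio(spec$hr_mean, spec$hr_sd,
                            duration = end_time + 2000,
                            fs = fs, finger_delay = spec$finger_delay,
                            seed = NULL, t0 = 0)
    base <- array(0, d)
    base[geo$brain] <- 0.75 * spec$m0a
    base[geo$csf] <- spec$m0a / spec$csf_factor
    tp <- tissue_params(spec$cbf, spec$dt_tiss)
    label_order <- rep(c("tag", "control"), timing$n_pairs)
    data <- vector("list", length(ti_order))
    vol_times <- vector("list", length(ti_order))
    phi_true <- vector("list", length(ti_order))
    noise_sd <- spec$noise_sd * spec$m0a
    n_slices <- d[3]
    ter_idx <- lapply(spec$territories$label, function(l) geo$labels == l)
    for (i in seq_along(ti_order)) {
      ti <- ti_order[i]
      tl <- starts[i] + (seq_len(n_vol) - 1) * timing$tr
      vol_times[[i]] <- tl
      arr <- array(0, c(d, n_vol))
      phim <- matrix(NA_real_, n_vol, n_slices)
      for (v in seq_len(n_vol)) {
        vol <- array(rep(base, 1), d)
        for (s in seq_len(n_slices)) {
          t_eff <- effective_ti(ti, s - 1, timing$slice_delay)
          t_acq <- tl[v] + t_eff
          phi <- cardiac_phase(t_acq, phys$beat_times, on_outside = "na")
          phim[v, s] <- phi
          if (label_order[v] == "tag" && !is.na(phi)) {
            pars <- phase_modulated_params(spec, phi)
            sl <- vol[, , s]
            # tissue background (and underlying parenchyma of artery voxels)
            dm_t <- .tissue_model(t_eff, spec$cbf, spec$dt_tiss,
                                  tp$lambda_bp, tp$t1t,
                                  1, spec$m0a, timing$quipss_cutoff, 1664)
            tis <- geo$brain[, , s] & !geo$csf[, , s]
            sl[tis] <- sl[tis] - dm_t
            for (k in seq_len(nrow(pars))) {
              idx <- ter_idx[[k]][, , s]
              if (any(idx)) {
                dm_a <- .arterial_model(t_eff, pars$abv[k], pars$dt[k],
                                        pars$sigma[k],
                                        timing$quipss_cutoff, 1, 1664,
                                        spec$m0a, "observation")
                sl[idx] <- sl[idx] - dm_a
              }
            }
            vol[, , s] <- sl
          }
        }
        if (noise_sd > 0)
          vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), d)
        arr[, , , v] <- vol
      }
      data[[i]] <- arr
      phi_true[[i]] <- phim
    }
    series <- asl_series(data, ti_order,
                         label_order = rep(list(label_order),
                                           length(ti_order)),
                         vol_times = vol_times,
                         slice_delay = timing$slice_delay, tr = timing$tr)
    calib <- base
    structure(list(series = series, physio = phys$trace, calib = calib,
                   bp = blood_pressures(spec$bp_sys, spec$bp_dia),
                   timing = timing, spec = spec,
                   truth = list(beat_times = phys$beat_times,
                                peak_times = phys$peak_times,
                                labels = geo$labels,
                                tissue_mask = geo$tissue,
                                csf_mask = geo$csf,
                                phi = phi_true,
                                ti_order = ti_order)),
              class = "asl_simulation")
  })
}

#' Microvascular contamination study
#'
#' Quantifies the bias from ignoring the tissue compartment at short
#' inversion times: for each (true aBV, tissue arrival time) pair, a
#' noiseless two-compartment difference curve is generated and the
#' arterial-only model is fitted at the short TIs; the relative
#' overestimation `100 * (fitted - true)/true` is reported.
#'
#' @param abv_grid True aBV values (%v).
#' @param dt_tiss_list Tissue arrival times (ms).
#' @param cbf Tissue perfusion (mL/100 g/min).
#' @param dt_art Arterial arrival time (ms); `NULL` derives it as
#'   `dt_tiss - 350` (the tissue bed lies 350 ms downstream of the large
#'   arteries), a scalar overrides it absolutely.
#' @param sigma_true Dispersion width of the simulated arterial bolus (ms);
#'   0 (plug flow) by default so the study isolates the microvascular
#'   contamination from dispersion effects.
#' @param ti_list Fitted inversion times (ms).
#' @param cfg A [fit_config()]; defaults to `fit_config()`.
#' @return data.frame with columns `abv_true`, `dt_tiss`, `dt_art`,
#'   `abv_fit`, `dt_fit`, `sigma_fit`, `overestimation_pct`.
#' @export
simulation_study <- function(abv_grid, dt_tiss_list = 700, cbf = 60,
                             dt_art = NULL, sigma_true = 0,
                             ti_list = seq(250, 850, by = 100),
                             cfg = NULL) {
  stopifnot(all(abv_grid > 0), all(abv_grid < 100))
  if (is.null(cfg)) cfg <- fit_config()
  rows <- list()
  for (dtt in dt_tiss_list) {
    da <- if (is.null(dt_art)) dtt - 350 else dt_art
    stopifnot(da >= 0)
    tp <- tissue_params(cbf, dtt)
    for (a in abv_grid) {
      p <- arterial_params(a, da, sigma_true, tau = cfg$tau,
                           alpha = cfg$alpha, t1a = cfg$t1a, m0a = cfg$m0a)
      dm <- two_compartment_signal(ti_list, p, tp, decay = cfg$decay)
      fit <- fit_voxel(ti_list, dm, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        abv_true = a, dt_tiss = dtt, dt_art = da,
        abv_fit = fit[["abv"]], dt_fit = fit[["dt"]],
        sigma_fit = fit[["sigma"]],
        overestimation_pct = 100 * (fit[["abv"]] - a) / a)
    }
  }
  do.call(rbind, rows)
}
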