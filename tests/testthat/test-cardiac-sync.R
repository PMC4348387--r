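# Peak detection, phase assignment, binning and balance accounting.

# series of 1x1x1 volumes: enough to exercise timing logic cheaply
tiny_series <- function(n_vol, ti = 250, tr = 1400, t_start = 5000,
                        n_slices = 1, slice_delay = 29,
                        values = NULL) {
  dat <- array(if (is.null(values)) 0 else values,
               c(1, 1, n_slices, n_vol))
  asl_series(list(dat), ti,
             label_order = list(rep(c("tag", "control"),
                                    length.out = n_vol)),
             vol_times = list(t_start + (seq_len(n_vol) - 1) * tr),
             slice_delay = slice_delay, tr = tr)
}

test_that("systolic peaks of a constructed waveform are found within a sample", {
  fs <- 100
  ts <- seq(-500, 2700, by = 1000 / fs)
  beats <- c(0, 1000, 2000)
  amp <- rowSums(sapply(beats, function(q) {
    r <- ts - q
    ifelse(r >= -100 & r <= 0, 0.5 * (1 + cos(pi * r / 100)),
           ifelse(r > 0 & r < 900, exp(-r / 300), 0))
  }))
  got <- detect_systolic_peaks(physio_trace(amp, fs, t0 = -500))
  expect_length(got, 3)
  expect_true(all(abs(got - beats) <= 1000 / fs + 1e-9))
})

test_that("a flat trace is rejected as unusable", {
  expect_error(detect_systolic_peaks(physio_trace(rep(1, 1000), 100)),
               "unusable")
})

test_that("detected inter-peak interval matches the generated heart rate", {
  g <- generate_physio(hr_mean = 65, hr_sd = 2, duration = 120000,
                       fs = 100, finger_delay = 0, seed = 11)
  peaks <- detect_systolic_peaks(g$trace)
  expect_lt(abs(mean(diff(peaks)) - 60000 / 65), 0.02 * 60000 / 65)
  # and the detected peaks align with the generator's known beats
  expect_lt(abs(length(peaks) - length(g$beat_times)), 3)
})

test_that("peak shift subtracts the peripheral delay and is invertible", {
  expect_equal(shift_peaks(c(1000, 2000), 225), c(775, 1775))
  p <- c(500, 1400, 2300)
  expect_equal(shift_peaks(p, 0), p)
  expect_equal(shift_peaks(shift_peaks(p, 225), -225), p)
})

test_that("cardiac phase interpolates linearly and stays in [0,1)", {
  peaks <- c(0, 1000, 2000)
  expect_equal(cardiac_phase(250, peaks), 0.25)
  expect_equal(cardiac_phase(0, peaks), 0)
  expect_equal(cardiac_phase(999.9, peaks), 0.9999)
  expect_equal(cardiac_phase(1000, peaks), 0)  # boundary belongs to next cycle
  expect_error(cardiac_phase(2500, peaks), "outside")
  expect_true(is.na(cardiac_phase(2500, peaks, on_outside = "na")))
  # irregular beats
  peaks2 <- c(0, 800, 2000)
  expect_equal(cardiac_phase(400, peaks2), 0.5)
  expect_equal(cardiac_phase(1400, peaks2), 0.5)
})

test_that("slice phases advance by slice_delay/RR at constant heart rate", {
  ser <- tiny_series(10, n_slices = 5)
  peaks <- seq(0, 40000, by = 1000)  # RR 1000 ms
  a <- assign_phases(ser, peaks, mode = "slice")
  phi <- a$per_ti[[1]]$phi
  for (s in 2:5) {
    expect_equal((phi[, s] - phi[, 1]) %% 1, rep(((s - 1) * 29 / 1000), 10),
                 tolerance = 1e-12)
  }
  expect_true(all(phi >= 0 & phi < 1))
})

test_that("label mode equals slice mode shifted back by (TI + s*delay)/RR", {
  ser <- tiny_series(8, ti = 450, n_slices = 4)
  peaks <- seq(0, 40000, by = 1000)
  sl <- assign_phases(ser, peaks, mode = "slice")$per_ti[[1]]$phi
  lb <- assign_phases(ser, peaks, mode = "label")$per_ti[[1]]$phi
  for (s in 1:4) {
    shift <- (450 + (s - 1) * 29) / 1000
    expect_equal(lb[, s], (sl[, s] - shift) %% 1, tolerance = 1e-9)
    # label-mode phase is the same for every slice of a volume
    expect_equal(lb[, s], lb[, 1])
  }
})

test_that("bin counts are conserved per TI and slice", {
  ser <- tiny_series(40, n_slices = 3)
  g <- generate_physio(70, 3, duration = 70000, fs = 100, finger_delay = 0,
                       seed = 3)
  a <- assign_phases(ser, g$beat_times, mode = "slice")
  b <- phase_binned_delta(ser, a)
  for (s in 1:3) {
    expect_equal(sum(b$per_ti[[1]]$n_tag[, s]), 20)
    expect_equal(sum(b$per_ti[[1]]$n_control[, s]), 20)
  }
  rep <- balance_report(b)
  expect_equal(sum(rep$n_tag) + sum(rep$n_control), 3 * 40)
})

test_that("binned difference is control mean minus tag mean", {
  # two volumes (one tag, one control) forced into the same bin
  dat <- array(0, c(2, 2, 1, 2))
  dat[, , 1, 1] <- 1    # tag
  dat[, , 1, 2] <- 3.5  # control
  ser <- asl_series(list(dat), 250, list(c("tag", "control")),
                    list(c(5000, 5700)), slice_delay = 0, tr = 700)
  peaks <- seq(0, 20000, by = 700)  # both volumes at identical phase
  a <- assign_phases(ser, peaks)
  b <- phase_binned_delta(ser, a)
  filled <- which(!is.na(b$per_ti[[1]]$delta_m), arr.ind = TRUE)
  expect_equal(nrow(filled), 4)  # one bin holds all four voxels
  expect_true(all(b$per_ti[[1]]$delta_m[!is.na(b$per_ti[[1]]$delta_m)] == 2.5))
})

test_that("identical tag and control series give zero difference, and dM is linear", {
  set.seed(42)
  vals <- rnorm(1 * 1 * 2 * 30)
  dat <- array(rep(vals[1:60], 1), c(1, 1, 2, 30))
  # make tag and control volumes identical pairwise
  for (v in seq(1, 29, 2)) dat[, , , v + 1] <- dat[, , , v]
  ser <- asl_series(list(dat), 250,
                    list(rep(c("tag", "control"), 15)),
                    list(5000 + (0:29) * 1400), slice_delay = 29, tr = 1400)
  g <- generate_physio(64, 0, duration = 60000, fs = 100, finger_delay = 0,
                       seed = 1)
  a <- assign_phases(ser, g$beat_times)
  b <- phase_binned_delta(ser, a)
  dm <- b$per_ti[[1]]$delta_m
  expect_true(all(abs(dm[!is.na(dm)]) < 1e-12))
  # linearity: scaling the images scales a non-trivial difference
  ser3 <- ser
  ser3$data[[1]] <- array(rnorm(length(dat)), dim(dat))
  b3 <- phase_binned_delta(ser3, a)
  ser4 <- ser3
  ser4$data[[1]] <- 2 * ser4$data[[1]]
  b4 <- phase_binned_delta(ser4, a)
  expect_equal(b4$per_ti[[1]]$delta_m, 2 * b3$per_ti[[1]]$delta_m)
})

test_that("a heart rate locked to TR collapses all volumes into one bin", {
  ser <- tiny_series(32, ti = 250, tr = 1400)
  peaks <- seq(0, 80000, by = 700)  # RR = TR/2: every volume at equal phase
  a <- assign_phases(ser, peaks)
  b <- phase_binned_delta(ser, a)
  occupied <- which(b$per_ti[[1]]$n_tag[, 1] > 0)
  expect_length(occupied, 1)
  rep <- balance_report(b, floor = 3)
  expect_true(all(rep$flagged[rep$n_tag == 0]))
})

test_that("counts flatten toward n_pairs/n_bins for incommensurate rates", {
  ser <- tiny_series(400, tr = 1400)
  rr <- 1000 * sqrt(2) / sqrt(2.02)  # irrational-looking ratio vs TR
  peaks <- seq(0, 400 * 1400 + 10000, by = rr)
  a <- assign_phases(ser, peaks)
  b <- phase_binned_delta(ser, a)
  expect_true(all(abs(b$per_ti[[1]]$n_tag[, 1] - 200 / 8) <= 8))
})

test_that("out-of-trace volumes are dropped, not fatal", {
  ser <- tiny_series(10, t_start = 0)  # starts before the first peak
  peaks <- seq(6000, 30000, by = 1000)
  expect_message(a <- assign_phases(ser, peaks), "dropped")
  expect_gt(a$n_dropped, 0)
  expect_true(all(is.na(a$per_ti[[1]]$phi[!a$per_ti[[1]]$keep])))
})

test_that("slice-stack phase offset reproduces the 0.406 arithmetic", {
  expect_equal(slice_stack_phase_offset(14, 29, 1000), 0.406)
  expect_gt(slice_stack_phase_offset(14, 29, 1000), 0.4)
})
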