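# Synthetic acquisition generator and the contamination study.

test_that("generated physio is periodic at hr_sd = 0 and delay shifts peaks", {
  g <- generate_physio(60, 0, duration = 10000, fs = 100, finger_delay = 0,
                       seed = 1)
  expect_equal(diff(g$beat_times), rep(1000, length(g$beat_times) - 1))
  expect_equal(g$peak_times, g$beat_times)
  g2 <- generate_physio(60, 0, duration = 10000, fs = 100,
                        finger_delay = 225, seed = 1)
  expect_equal(g2$peak_times, g2$beat_times + 225)
})

test_that("beat intervals center on 60000/hr_mean", {
  g <- generate_physio(65, 3, duration = 300000, fs = 50, seed = 2)
  rr <- diff(g$beat_times)
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 60000 / 65), 3 * se + 1e-9)
  expect_lt(abs(mean(rr) - 60000 / 65), 0.02 * 60000 / 65)
})

test_that("generator is deterministic under a fixed seed", {
  g1 <- generate_physio(65, 3, duration = 20000, fs = 50, seed = 9)
  g2 <- generate_physio(65, 3, duration = 20000, fs = 50, seed = 9)
  expect_identical(g1, g2)
  s1 <- simulate_acquisition(small_phantom(noise_sd = 0.001),
                             small_timing(n_pairs = 4), seed = 3)
  s2 <- simulate_acquisition(small_phantom(noise_sd = 0.001),
                             small_timing(n_pairs = 4), seed = 3)
  expect_identical(s1$series$data, s2$series$data)
  expect_identical(s1$truth$beat_times, s2$truth$beat_times)
})

test_that("phase modulation hits its anchors and brackets them", {
  spec <- small_phantom()
  dia <- phase_modulated_params(spec, 1.5 / 8)
  sys <- phase_modulated_params(spec, 6.5 / 8)
  expect_equal(dia$abv, spec$territories$abv_dia)
  expect_equal(dia$dt, spec$territories$dt_dia)
  expect_equal(dia$sigma, spec$territories$sigma_dia)
  expect_equal(sys$abv, spec$territories$abv_sys)
  expect_equal(sys$dt, spec$territories$dt_sys)
  phis <- seq(0, 0.999, by = 0.001)
  curve <- sapply(phis, function(ph) phase_modulated_params(spec, ph)$abv[1])
  expect_gte(min(curve), spec$territories$abv_dia[1] - 1e-12)
  expect_lte(max(curve), spec$territories$abv_sys[1] + 1e-12)
  # continuity across the wrap-around (bounded by the local slope)
  expect_lt(abs(phase_modulated_params(spec, 0.9995)$abv[1] -
                  phase_modulated_params(spec, 0.0005)$abv[1]), 5e-3)
})

test_that("zero-noise simulation reproduces the analytic difference signal", {
  spec <- small_phantom(noise_sd = 0)
  timing <- small_timing(n_pairs = 3)
  sim <- simulate_acquisition(spec, timing, seed = 4)
  ser <- sim$series
  i <- 1
  ti <- ser$ti[i]
  lab <- ser$label_order[[i]]
  v_tag <- which(lab == "tag")[2]
  v_ctl <- which(lab == "control")[2]
  # voxel inside the first territory, slice 3
  vox <- which(sim$truth$labels[, , 3] == 1L, arr.ind = TRUE)[1, ]
  s <- 3
  t_eff <- effective_ti(ti, s - 1, timing$slice_delay)
  phi <- sim$truth$phi[[i]][v_tag, s]
  pars <- phase_modulated_params(spec, phi)
  expected <- arterial_delta_m(
    t_eff, arterial_params(pars$abv[1], pars$dt[1], pars$sigma[1],
                           tau = timing$quipss_cutoff)) +
    tissue_delta_m(t_eff, tissue_params(spec$cbf, spec$dt_tiss),
                   tau = timing$quipss_cutoff)
  got <- ser$data[[i]][vox[1], vox[2], s, v_ctl] -
    ser$data[[i]][vox[1], vox[2], s, v_tag]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("tag equals control when both compartments are empty", {
  spec <- small_phantom(noise_sd = 0, cbf = 0)
  spec$territories$abv_dia[] <- 0
  spec$territories$abv_sys[] <- 0
  spec2 <- phantom_spec(dim = spec$dim, territories = spec$territories,
                        territory_slices = spec$territory_slices,
                        cbf = 0, noise_sd = 0)
  sim <- simulate_acquisition(spec2, small_timing(n_pairs = 2), seed = 5)
  dat <- sim$series$data[[1]]
  expect_equal(dat[, , , 1], dat[, , , 2])
})

test_that("contamination vanishes without tissue and decreases with aBV and dt_tiss", {
  clean <- simulation_study(c(1, 2, 5), dt_tiss_list = 700, cbf = 0)
  expect_lt(max(abs(clean$overestimation_pct)), 0.01)
  tab <- simulation_study(c(1.2, 2, 3, 5, 8), dt_tiss_list = c(700, 800))
  for (dtt in c(700, 800)) {
    ov <- tab$overestimation_pct[tab$dt_tiss == dtt]
    expect_true(all(diff(ov) < 0))          # decreasing in aBV
    expect_true(all(ov > 0))                # it is an overestimation
  }
  for (a in c(1.2, 2, 3, 5, 8)) {
    ov <- tab$overestimation_pct[tab$abv_true == a]
    expect_true(all(diff(ov) < 0))          # decreasing in tissue arrival
  }
  # a contaminant arriving after the last fitted TI cannot bias the fit
  late <- simulation_study(c(1.2, 3), dt_tiss_list = 900)
  expect_lt(max(abs(late$overestimation_pct)), 1e-6)
})

test_that("sync + fit recovers a constant-parameter phantom to optimizer tolerance", {
  spec <- small_phantom(noise_sd = 0, cbf = 0, dt_sys_offset = 0,
                        sigma_dia_offset = 0)
  spec$territories$ac[] <- 0
  spec <- phantom_spec(dim = spec$dim, territories = spec$territories,
                       territory_slices = spec$territory_slices,
                       cbf = 0, noise_sd = 0, dt_sys_offset = 0,
                       sigma_dia_offset = 0)
  timing <- small_timing(n_pairs = 12)
  sim <- simulate_acquisition(spec, timing, seed = 6)
  peaks <- detect_systolic_peaks(sim$physio)
  assign <- assign_phases(sim$series, shift_peaks(peaks, spec$finger_delay))
  binned <- phase_binned_delta(sim$series, assign)
  mask <- sim$truth$labels > 0L
  pm <- fit_maps(binned, fit_config(m0a = spec$m0a), mask = mask,
                 bins = c(2, 7))
  for (k in 1:5) {
    idx <- sim$truth$labels == k & !is.na(pm$maps$bin2$abv)
    expect_gt(sum(idx), 0)
    tr <- spec$territories[k, ]
    expect_lt(max(abs(pm$maps$bin2$abv[idx] - tr$abv_dia)) / tr$abv_dia,
              0.01)
    expect_lt(max(abs(pm$maps$bin2$dt[idx] - tr$dt_dia)), 5)
    expect_lt(max(abs(pm$maps$bin2$sigma[idx] - tr$sigma_dia)), 5)
  }
})
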