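# Independent numerical oracles and shared fixtures, built in code.

erf_ref <- function(x) 2 * pnorm(sqrt(2) * x) - 1

# brute-force convolution of the square bolus with a unit-area Gaussian on a
# fine grid (0.01 ms), independent of the closed form under test
oracle_dispersed <- function(t, dt, tau, sigma, h = 0.01) {
  s <- seq(dt, dt + tau, by = h)
  f <- dnorm(t - s, 0, sigma)
  (sum(f) - 0.5 * (f[1] + f[length(f)])) * h  # trapezoid rule
}

# quadrature oracle for the single-compartment tissue model
oracle_tissue <- function(t, cbf, dt_tiss, lambda = 0.9, t1t = 1330,
                          t1a = 1664, tau = 700, alpha = 1, m0a = 1) {
  f <- cbf / (100 * 60 * 1000)
  t1app <- 1 / (1 / t1t + f / lambda)
  if (t <= dt_tiss) return(0)
  b <- min(t, dt_tiss + tau)
  v <- integrate(function(s) exp(-s / t1a) * exp(-(t - s) / t1app),
                 dt_tiss, b, rel.tol = 1e-12)$value
  2 * alpha * m0a * f * v
}

# quadrature oracle for the decay-in-kernel arterial model
oracle_arterial_kernel <- function(t, abv, dt, sigma, tau = 700,
                                   alpha = 1, t1a = 1664, m0a = 1) {
  v <- integrate(function(s) exp(-s / t1a) * dnorm(t - s, 0, sigma),
                 dt, dt + tau, rel.tol = 1e-12)$value
  2 * alpha * (abv / 100) * m0a * v
}

# compact phantom for pipeline-level tests: 12x12x5 grid, five small
# territory blobs on slices 2-4, CSF blob on slice 5
small_phantom <- function(noise_sd = 0, ...) {
  terr <- data.frame(
    name = c("RMCA", "LMCA", "ACA", "RPCA", "LPCA"),
    label = 1:5,
    cx = c(3, 9, 6, 4, 8),
    cy = c(7, 7, 10, 3, 3),
    radius = 1.5,
    abv_dia = c(2.0, 2.2, 1.8, 1.6, 1.68),
    ac = c(0.57, 0.50, 0.43, 1.1, 1.1),
    dt_dia = c(430, 435, 460, 445, 445),
    sigma_sys = c(80, 85, 90, 85, 85))
  phantom_spec(dim = c(12, 12, 5), territories = terr,
               territory_slices = 2:4, noise_sd = noise_sd, ...)
}

small_timing <- function(n_pairs = 20, n_slices = 5, ...) {
  asl_timing(n_pairs = n_pairs, n_slices = n_slices, ...)
}

# per-image noise s.d. giving a target SNR in the phase-binned difference
# images: SNR = peak binned dM / sd(binned dM), with ~n_pairs/n_bins tag and
# control images per bin
noise_for_snr <- function(spec, timing, snr, n_bins = 8) {
  peak_dm <- 2 * mean(spec$territories$abv_dia) / 100 * spec$m0a *
    exp(-750 / 1664)
  n_per_bin <- timing$n_pairs / n_bins
  peak_dm / (snr * sqrt(2 / n_per_bin))
}

# cached end-to-end run shared by pipeline and acceptance tests
.e2e_cache <- new.env(parent = emptyenv())
e2e_result <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  spec <- small_phantom()
  timing <- small_timing(n_pairs = 40)
  spec <- small_phantom(noise_sd = noise_for_snr(spec, timing, snr = 50))
  sim <- simulate_acquisition(spec, timing, seed = 7L)
  res <- run_pipeline(sim$series, sim$physio, sim$bp, sim$truth$labels,
                      label_names = setNames(spec$territories$label,
                                             spec$territories$name),
                      calib = sim$calib, csf_mask = sim$truth$csf_mask,
                      percentile = 60, bins = c(2, 7),
                      csf_factor = spec$csf_factor)
  .e2e_cache$res <- list(spec = spec, timing = timing, sim = sim, res = res)
  .e2e_cache$res
}
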