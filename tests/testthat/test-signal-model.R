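# Kinetic model: square and dispersed bolus, arterial and tissue signals.

test_that("square bolus is 1 on the half-open bolus interval and 0 outside", {
  expect_equal(square_bolus(500, dt = 300, tau = 700), 1)
  expect_equal(square_bolus(200, dt = 300, tau = 700), 0)
  expect_equal(square_bolus(1000, dt = 300, tau = 700), 0)  # trailing edge
  expect_equal(square_bolus(300, dt = 300, tau = 700), 1)   # leading edge
  expect_error(square_bolus(500, dt = 300, tau = 0), "invalid bolus")
})

test_that("dispersed bolus matches the brute-force convolution oracle", {
  cases <- expand.grid(t = c(250, 350, 650, 900, 1100),
                       sigma = c(20, 50, 120))
  for (i in seq_len(nrow(cases))) {
    got <- dispersed_bolus(cases$t[i], dt = 300, tau = 700,
                           sigma = cases$sigma[i])
    want <- oracle_dispersed(cases$t[i], dt = 300, tau = 700,
                             sigma = cases$sigma[i])
    expect_lt(abs(got - want), 1e-9)
  }
})

test_that("dispersed bolus has the leading-edge value 1/2 and sigma = 0 limit", {
  expect_equal(dispersed_bolus(300, dt = 300, tau = 700, sigma = 50), 0.5,
               tolerance = 1e-12)
  t <- seq(0, 1500, by = 10)
  expect_identical(dispersed_bolus(t, 300, 700, 0), square_bolus(t, 300, 700))
  # away from +/- 3 sigma of the edges the small-sigma kernel matches plug flow
  for (sg in c(10, 1, 0.1)) {
    keep <- abs(t - 300) > 3 * sg & abs(t - 1000) > 3 * sg
    expect_lt(max(abs(dispersed_bolus(t[keep], 300, 700, sg) -
                        square_bolus(t[keep], 300, 700))), 2e-3)
  }
  expect_error(dispersed_bolus(500, 300, 700, -1), "invalid dispersion")
})

test_that("dispersed bolus conserves the label mass integral tau", {
  for (sg in c(0, 20, 80, 200)) {
    mass <- integrate(function(t) dispersed_bolus(t, 300, 700, sg),
                      -2000, 4000, rel.tol = 1e-10,
                      subdivisions = 400)$value
    expect_equal(mass, 700, tolerance = 1e-6 * 700)
  }
})

test_that("arterial signal follows the plateau closed form", {
  p <- arterial_params(abv = 2, dt = 300, sigma = 0, tau = 700)
  expect_equal(arterial_delta_m(600, p), 2 * 0.02 * exp(-600 / 1664))
  expect_equal(arterial_delta_m(600, p), 0.02789, tolerance = 1e-4)
  expect_equal(arterial_delta_m(200, p), 0)            # before arrival
  t <- seq(300, 999, by = 33)
  expect_equal(arterial_delta_m(t, p),
               2 * 1 * (2 / 100) * 1 * exp(-t / 1664))  # exact on plateau
  p0 <- arterial_params(abv = 0, dt = 300, sigma = 50)
  expect_true(all(arterial_delta_m(seq(0, 2000, 100), p0) == 0))
})

test_that("arterial signal decays faster with shorter blood T1", {
  t <- 600
  p_long <- arterial_params(2, 300, 0, t1a = 1664)
  p_short <- arterial_params(2, 300, 0, t1a = 1200)
  expect_gt(arterial_delta_m(t, p_long), arterial_delta_m(t, p_short))
})

test_that("decay-in-kernel arterial variant matches its quadrature oracle", {
  p <- arterial_params(abv = 3, dt = 400, sigma = 90)
  for (t in c(450, 700, 1000, 1300)) {
    expect_equal(arterial_delta_m(t, p, decay = "kernel"),
                 oracle_arterial_kernel(t, 3, 400, 90), tolerance = 1e-10)
  }
  # both conventions coincide when there is no dispersion
  p0 <- arterial_params(abv = 3, dt = 400, sigma = 0)
  t <- seq(0, 1500, 50)
  expect_equal(arterial_delta_m(t, p0, decay = "kernel"),
               arterial_delta_m(t, p0, decay = "observation"))
})

test_that("tissue signal is zero before arrival and matches quadrature", {
  tp <- tissue_params(cbf = 60, dt_tiss = 800)
  expect_equal(tissue_delta_m(c(0, 400, 800), tp), c(0, 0, 0))
  tp0 <- tissue_params(cbf = 0, dt_tiss = 800)
  expect_true(all(tissue_delta_m(seq(0, 2500, 100), tp0) == 0))
  for (t in c(850, 900, 1200, 1600, 2400)) {
    expect_equal(tissue_delta_m(t, tp), oracle_tissue(t, 60, 800),
                 tolerance = 1e-6)
  }
  # continuity across the arrival time
  eps <- 1e-6
  expect_lt(abs(tissue_delta_m(800 + eps, tp) - tissue_delta_m(800 - eps, tp)),
            1e-9)
})

test_that("two-compartment signal is additive", {
  p <- arterial_params(3, 450, 60)
  tp <- tissue_params(60, 800)
  t <- seq(250, 2500, by = 250)
  expect_equal(two_compartment_signal(t, p, tp),
               arterial_delta_m(t, p) + tissue_delta_m(t, tp))
  expect_equal(two_compartment_signal(t, p, tissue_params(0, 800)),
               arterial_delta_m(t, p))
  expect_equal(two_compartment_signal(t, arterial_params(0, 450, 60), tp),
               tissue_delta_m(t, tp))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(arterial_params(-1, 300, 50))
  expect_error(arterial_params(2, 300, 50, tau = -5), "invalid bolus")
  expect_error(arterial_params(2, 300, 50, alpha = 1.5))
  expect_error(tissue_params(-10, 800))
})
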