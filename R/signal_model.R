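# Kinetic models of the short-TI PASL difference signal: a dispersed
# plug-flow macrovascular (arterial) compartment, and a single-compartment
# tissue model used by the simulator and the contamination study.
# All times are milliseconds; aBV is carried in percent of voxel volume (%v)
# throughout the API and converted to a fraction only inside signal evaluation.

# error function via the normal CDF
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Arterial compartment parameters
#'
#' Bundles the parameters of the macrovascular PASL signal model: the labeled
#' blood occupying a fraction of the voxel decays with the T1 of arterial
#' blood and passes the voxel as a dispersed bolus of fixed duration.
#'
#' @param abv Arterial blood volume, in percent of voxel volume (%v).
#' @param dt Bolus arrival time \eqn{\Delta t} (ms): time for the leading edge
#'   of the labeled bolus to reach the voxel.
#' @param sigma Dispersion width \eqn{\sigma} (ms): standard deviation of the
#'   Gaussian kernel smearing the bolus edges.
#' @param tau Bolus duration \eqn{\tau} (ms); fixed by the QUIPSS II cut-off
#'   in the intended protocol (700 ms).
#' @param alpha Labeling efficiency, in (0, 1].
#' @param t1a Longitudinal relaxation time of arterial blood (ms); 1664 ms at
#'   3 T.
#' @param m0a Equilibrium magnetization of arterial blood, arbitrary signal
#'   units.
#' @return An object of class `arterial_params`.
#' @seealso [arterial_delta_m()]
#' @export
arterial_params <- function(abv, dt, sigma, tau = 700, alpha = 1,
                            t1a = 1664, m0a = 1) {
  stopifnot(abv >= 0, dt >= 0, sigma >= 0, alpha > 0, alpha <= 1,
            t1a > 0, m0a > 0)
  if (tau <= 0) stop("invalid bolus: tau must be positive")
  structure(list(abv = abv, dt = dt, sigma = sigma, tau = tau,
                 alpha = alpha, t1a = t1a, m0a = m0a),
            class = "arterial_params")
}

#' Tissue compartment parameters
#'
#' Parameters of the single-compartment tissue kinetic model, used only by
#' the simulator and the microvascular-contamination study: at short
#' inversion times the pipeline fits the arterial model alone.
#'
#' @param cbf Tissue perfusion, mL/100 g/min.
#' @param dt_tiss Arrival time of the label at the capillary bed (ms).
#' @param lambda_bp Blood-tissue partition coefficient, mL/g.
#' @param t1t Tissue longitudinal relaxation time (ms); gray matter at 3 T.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(cbf, dt_tiss, lambda_bp = 0.9, t1t = 1330) {
  stopifnot(cbf >= 0, dt_tiss >= 0, lambda_bp > 0, t1t > 0)
  structure(list(cbf = cbf, dt_tiss = dt_tiss, lambda_bp = lambda_bp,
                 t1t = t1t),
            class = "tissue_params")
}

#' Square bolus weighting function
#'
#' Plug-flow weighting of the labeled bolus: 1 while the undispersed bolus
#' occupies the voxel, 0 otherwise. The interval is half-open,
#' `dt <= t < dt + tau`, so the bolus integral is exactly `tau`.
#'
#' @param t Time since labeling (ms); vectorized.
#' @param dt Bolus arrival time (ms).
#' @param tau Bolus duration (ms), positive.
#' @return 0/1 weights, same length as `t`.
#' @export
square_bolus <- function(t, dt, tau) {
  if (tau <= 0) stop("invalid bolus: tau must be positive")
  as.numeric(t >= dt & t < dt + tau)
}

#' Dispersed bolus weighting function
#'
#' The square bolus convolved with a unit-area Gaussian kernel of standard
#' deviation `sigma`, giving the closed form
#' \deqn{c(t) = \tfrac12\left[\mathrm{erf}\!\left(\frac{t-\Delta t}{\sigma\sqrt2}\right)
#'  - \mathrm{erf}\!\left(\frac{t-\Delta t-\tau}{\sigma\sqrt2}\right)\right].}
#' At `sigma = 0` it reduces exactly to [square_bolus()].
#'
#' @inheritParams square_bolus
#' @param sigma Dispersion width (ms), non-negative.
#' @return Weights in \[0, 1\], same length as `t`.
#' @export
dispersed_bolus <- function(t, dt, tau, sigma) {
  if (tau <= 0) stop("invalid bolus: tau must be positive")
  if (sigma < 0) stop("invalid dispersion: sigma must be non-negative")
  if (sigma == 0) return(square_bolus(t, dt, tau))
  s2 <- sigma * sqrt(2)
  0.5 * (erf((t - dt) / s2) - erf((t - dt - tau) / s2))
}

# shared evaluator used by arterial_delta_m and the voxel fitter, taking
# bare numeric parameters so the optimizer avoids list construction.
# decay = "observation": T1 decay applied at observation time t (default);
# decay = "kernel": decay inside the convolution integral, closed form
# obtained by completing the square in the Gaussian.
.arterial_model <- function(t, abv, dt, sigma, tau, alpha, t1a, m0a,
                            decay = c("observation", "kernel")) {
  decay <- match.arg(decay)
  amp <- 2 * alpha * (abv / 100) * m0a
  if (decay == "observation" || sigma == 0) {
    out <- amp * exp(-t / t1a) * dispersed_bolus(t, dt, tau, sigma)
    if (decay == "kernel" && sigma == 0) return(out)
    if (decay == "observation") return(out)
  }
  # int_dt^{dt+tau} exp(-s/T1) N(t - s; 0, sigma) ds
  #   = exp(sigma^2/(2 T1^2) - t/T1) * [Phi-terms at m = t - sigma^2/T1]
  m <- t - sigma^2 / t1a
  s2 <- sigma * sqrt(2)
  amp * exp(sigma^2 / (2 * t1a^2) - t / t1a) *
    0.5 * (erf((m - dt) / s2) - erf((m - dt - tau) / s2))
}

#' Arterial difference signal
#'
#' The tag/control difference signal of the macrovascular compartment:
#' \deqn{\Delta M(t) = 2\,\alpha\,\frac{aBV}{100}\,M_{0,a}\,e^{-t/T_{1,a}}\,c(t)}
#' with \eqn{c(t)} the dispersed bolus weighting ([dispersed_bolus()]).
#' By default T1 decay is applied at observation time, outside the
#' convolution; `decay = "kernel"` instead decays the label inside the
#' convolution integral (closed form). The two agree at `sigma = 0` and
#' differ by a factor `exp(sigma^2/(2 T1a^2))` in amplitude, negligible for
#' physiological dispersion widths.
#'
#' @param t Time since labeling (ms); vectorized.
#' @param p An [arterial_params()] object.
#' @param decay `"observation"` (default) or `"kernel"`.
#' @return Signal in the units of `m0a`.
#' @export
arterial_delta_m <- function(t, p, decay = c("observation", "kernel")) {
  stopifnot(inherits(p, "arterial_params"), all(t >= 0))
  .arterial_model(t, p$abv, p$dt, p$sigma, p$tau, p$alpha, p$t1a, p$m0a,
                  match.arg(decay))
}

# closed-form single-compartment tissue kinetics, bare-parameter version
.tissue_model <- function(t, cbf, dt_tiss, lambda_bp, t1t,
                          alpha, m0a, tau, t1a) {
  f <- cbf / (100 * 60 * 1000)          # mL blood / g tissue / ms
  t1app <- 1 / (1 / t1t + f / lambda_bp)
  a <- 1 / t1a - 1 / t1app
  b <- pmin(t, dt_tiss + tau)
  out <- numeric(length(t))
  ok <- t > dt_tiss & cbf > 0
  if (any(ok)) {
    e <- if (abs(a) > 1e-12) {
      exp(-t[ok] / t1app) * (exp(-a * dt_tiss) - exp(-a * b[ok])) / a
    } else {
      exp(-t[ok] / t1app) * (b[ok] - dt_tiss)
    }
    out[ok] <- 2 * alpha * m0a * f * e
  }
  out
}

#' Tissue difference signal
#'
#' Single-compartment pulsed-ASL kinetic model: plug-flow delivery
#' `exp(-s/T1a)` on `[dt_tiss, dt_tiss + tau)` convolved with the tissue
#' residue/relaxation function `exp(-(t-s)/T1app)` where
#' `1/T1app = 1/T1t + f/lambda`. Evaluated in closed form. Used by the
#' simulator and the contamination study only; the voxel fitter never
#' includes this compartment.
#'
#' @param t Time since labeling (ms); vectorized.
#' @param tp A [tissue_params()] object.
#' @param alpha Labeling efficiency.
#' @param m0a Equilibrium magnetization of arterial blood.
#' @param tau Bolus duration (ms).
#' @param t1a T1 of arterial blood (ms).
#' @return Signal in the units of `m0a`; zero before `dt_tiss`.
#' @export
tissue_delta_m <- function(t, tp, alpha = 1, m0a = 1, tau = 700,
                           t1a = 1664) {
  stopifnot(inherits(tp, "tissue_params"), all(t >= 0))
  .tissue_model(t, tp$cbf, tp$dt_tiss, tp$lambda_bp, tp$t1t,
                alpha, m0a, tau, t1a)
}

#' Two-compartment difference signal
#'
#' Additive sum of the arterial ([arterial_delta_m()]) and tissue
#' ([tissue_delta_m()]) difference signals, sharing `alpha`, `m0a`, `tau`
#' and `t1a` from the arterial parameter set. Used to simulate voxels
#' containing both a large artery and perfused parenchyma.
#'
#' @inheritParams arterial_delta_m
#' @param tp A [tissue_params()] object.
#' @return Signal in the units of `m0a`.
#' @export
two_compartment_signal <- function(t, p, tp,
                                   decay = c("observation", "kernel")) {
  arterial_delta_m(t, p, decay) +
    tissue_delta_m(t, tp, alpha = p$alpha, m0a = p$m0a, tau = p$tau,
                   t1a = p$t1a)
}
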