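---
title: "Measuring cerebral arterial compliance with short-TI PASL: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cerebral arterial compliance with short-TI PASL: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslcompliance)
```

## The measurement problem

Arterial compliance — the change in arterial blood volume per unit change
in blood pressure — protects the cerebral microvasculature from pulsatile
stress, and its loss is implicated in small-vessel disease. It is hard to
measure intracranially: ultrasound echotracking is blocked by the skull,
and transcranial Doppler measures velocity, not geometry. Short inversion
time PASL offers a noninvasive route: below TI ≈ 1 s the labeled blood is
still inside the large arteries, so the tag/control difference signal ΔM is
essentially an image of arterial blood volume (aBV). Because arteries
distend with each heartbeat, sorting slice acquisitions by cardiac phase
and fitting a kinetic model per phase yields diastolic and systolic aBV,
and with the cuff pulse pressure, compliance:

$$AC = 100\,\frac{aBV_{sys}-aBV_{dia}}{aBV_{dia}\cdot PP}\quad[\%/\mathrm{mm\,Hg}].$$

## The kinetic model

The macrovascular compartment assumes plug flow with Gaussian dispersion:

$$\Delta M(t) = 2\,\alpha\,\frac{aBV}{100}\,M_{0,a}\,e^{-t/T_{1,a}}\,c(t),
\qquad
c(t)=\tfrac12\!\left[\operatorname{erf}\!\frac{t-\Delta t}{\sigma\sqrt2}
-\operatorname{erf}\!\frac{t-\Delta t-\tau}{\sigma\sqrt2}\right],$$

i.e. a square bolus of duration $\tau$ convolved with a unit-area Gaussian
of width $\sigma$. The square bolus uses the half-open support
$[\Delta t, \Delta t+\tau)$ so that its integral is exactly $\tau$ — the
choice is immaterial once dispersion is applied but makes label-mass
conservation exact in the $\sigma=0$ limit.

**Where the T1 decay acts.** We apply $e^{-t/T_{1,a}}$ at the observation
time, outside the convolution; the package also implements the
decay-inside-the-kernel variant in closed form (`decay = "kernel"`,
obtained by completing the square in the Gaussian). The two differ only by
a factor $e^{\sigma^2/2T_{1,a}^2}$ — about 0.2% at $\sigma = 100$ ms — so
the choice cannot be resolved from data and the simpler form is the
default.

**Fixed constants.** $\tau = 700$ ms is pinned by the QUIPSS II saturation
cut-off and is never fitted, including for TIs shorter than
$\Delta t+\tau$, where the trailing edge is simply not yet visible;
$\alpha = 1$; $T_{1,a} = 1664$ ms (arterial blood at 3 T). $M_{0,a}$ is
calibrated as the CSF median of a fully relaxed calibration image times a
conversion factor (default 0.87, a proton-density-ratio convention; the
argument is exposed because the factor depends on the calibration
protocol).

**Tissue compartment.** For simulation and contamination analysis only, a
single-compartment kinetic model is used: plug-flow delivery
$e^{-s/T_{1,a}}$ on $[\Delta t_{tiss},\Delta t_{tiss}+\tau)$ convolved with
the residue/relaxation function $e^{-(t-s)/T_1^{app}}$,
$1/T_1^{app} = 1/T_{1,t} + f/\lambda$, evaluated in closed form with
$\lambda = 0.9$ mL/g and $T_{1,t} = 1330$ ms (3 T gray matter; both
config-exposed). We also evaluated a variant in which the tissue sees the
same Gaussian-dispersed input as the artery; it *increases* the
contamination bias (dispersion moves label delivery earlier as well as
later), and was rejected in favor of the standard model. The voxel fitter
never includes this compartment — at short TIs its signal is small, and the
contamination study quantifies exactly how small.

## Retrospective cardiac synchronization

Systolic peaks are detected on a 0.5–8 Hz band-passed (zero-phase
Butterworth) plethysmograph trace as threshold-crossing local maxima with a
250 ms refractory period, then refined on the raw trace (the band-pass can
skew asymmetric pulse shapes by a few samples). The peripheral transit
delay — 225 ms by default, configurable — is subtracted so peaks mark the
cardiac events seen by the cerebral arteries. The normalized cardiac phase
of a slice acquired at $t_{acq}$ between consecutive peaks $t_1 < t_2$ is
$(t_{acq}-t_1)/(t_2-t_1)$, advancing linearly from 0 to 1 and resetting.

Phases are binned into eight half-open intervals $[k/8,(k+1)/8)$; "early
diastole" is the second bin and "early systole" the seventh. Half-open
edges guarantee a partition (published bin listings for this protocol are
ambiguous at the edges). Each slice is phased at its own acquisition time,
`t_label + TI + s·slice_delay` (29 ms per slice); the alternative `label`
mode phases every slice at the labeling time, which is how one verifies
that the signal follows the cardiac phase of the *imaging* slice rather
than of the label — across 14 slices the stack accumulates
`14 × 29 / RR ≈ 0.41` phase units at RR = 1000 ms, a shift that is visible
in label-sorted maps and absent in slice-sorted ones. Per (TI, bin, slice),
ΔM is the mean control image minus the mean tag image; cells missing
either label are represented as `NA`, never errors, and tag/control counts
are reported so synchronization bias can be audited. Volumes falling
outside the physio trace are dropped with a message. Tag/control identity
always comes from acquisition metadata, never from image intensities.

## Voxel-wise fitting

Three parameters (aBV in %v, $\Delta t$, $\sigma$) are fitted per voxel and
bin by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, the direct
analogue of MATLAB's `lsqcurvefit`) on one ΔM value per TI (7 points),
using slice-delay-corrected effective TIs. Choices the published protocol
leaves open, all config-exposed:

* **Bounds** aBV ∈ [0, 100] %v, Δt ∈ [0, 1500] ms, σ ∈ [0, 500] ms.
* **Initialization** (deterministic, no random restarts): aBV from the peak
  ΔM via the undispersed plateau form, Δt from the earliest TI whose ΔM
  exceeds 10% of the maximum, σ = 50 ms.
* **Degenerate inputs**: fewer than 4 finite points → voxel flagged unfit
  (`NA`); non-positive signal → aBV = 0 exactly; optimizer failure is
  caught per voxel and never aborts a map.
* **Tolerances**: `ftol = ptol = 1e-12`, so noiseless fits recover
  parameters to optimizer precision (residuals < 1e-8 of signal scale).
* **rmse** is the residual standard error $\sqrt{RSS/(n-3)}$, which is an
  unbiased estimate of the noise level on model-generated data.

Fitted aBV scales linearly with the data when $M_{0,a}$ is fixed and is
invariant when both are scaled together; these invariances are tested.

## ROIs and territory summaries

The artery mask keeps, per slice independently, the voxels strictly above
that slice's 95th-percentile intensity in the mean ΔM image of the
TI = 750 ms series (the TI with maximal raw difference intensity in the
intended protocol). Strict inequality keeps tie counts minimal. Territory
ROIs are the intersection of this mask with broad labeled masks (drawn
manually in vivo; emitted by the phantom in simulation), with a single ACA
label. Summaries are per-territory *medians*, optionally restricted to the
slice just above the circle of Willis (a config index; it varies by
subject). Median-of-voxelwise-AC is used rather than AC-of-median-aBVs; the
maps are also returned so the alternative is one line of user code.

## The synthetic acquisition generator

The generator is first-class, tested code that emulates the study
conditions: seven TIs 250–850 ms acquired as separate series in
seed-randomized order, TR 1400 ms, 80 tag/control pairs per TI alternating
tag-first, 14 slices at 29 ms delay, heart rate 65 ± 3 bpm, a
plethysmograph whose raised-cosine/exponential pulses lag the cardiac
events by the same 225 ms the analysis removes, additive Gaussian noise on
tag and control images independently (the high-SNR large-vessel regime;
Rician effects are out of scope), and a calibration image whose CSF region
inverts the calibration factor. Territory blobs carry diastolic aBV in the
1.5–2.5 %v range of large-artery voxels; systolic arrival time exceeds
diastolic by 41 ms and diastolic dispersion exceeds systolic by 30 ms — the
physiological pattern the method is designed to detect — and systolic aBV
follows from the planted compliance and the phantom pulse pressure
(52.7 mm Hg). Arterial parameters vary with phase by a C1, periodic
piecewise raised-cosine anchored at the early-diastole and early-systole
bin centers, so bin means sit almost exactly on the anchors. The default
tissue background (60 mL/100 g/min, arrival 800 ms) deliberately
contaminates the arterial fit the way parenchyma does in vivo.

What the phantom does **not** emulate: realistic vascular geometry, motion
(the motion-correction stage is an identity hook), field inhomogeneity,
arrhythmia, or partial-volume structure. Passing tests therefore
demonstrate the correctness of the synchronization/fitting/compliance
chain under the stated acquisition physics, not robustness to scanner
artifacts.

## The contamination study

`simulation_study()` generates noiseless two-compartment curves and fits
the arterial-only model at the seven short TIs. With tissue perfusion
60 mL/100 g/min and tissue arrival 700 ms, the maximum relative aBV
overestimation over true aBV ∈ (1, 10] %v is ≈ 2.9%, decreasing
monotonically with aBV and with tissue arrival time, and identically zero
when the contaminant arrives after the last fitted TI. The simulated
arterial bolus is undispersed by default (`sigma_true = 0`) so the study
isolates microvascular contamination from dispersion effects; with
`sigma_true = 100` ms the maximum rises to ≈ 4.5%, still below 5%. For the
published worked example (true aBV 1.65 %v, arterial arrival 445 ms,
tissue arrival 700 ms) this implementation finds 2.6% overestimation at
the verified global least-squares minimum; the published figure for that
example (1.2%) is inconsistent with its own surrounding arithmetic (an
aBV of 1.68 %v against a true 1.65 %v implies 1.8%), and depends on
unprinted tissue-model constants, so we report what the model actually
yields rather than matching the quoted number.

## Problem sizes and numerical conventions in the test suite

Tests run on a 12×12×5 phantom (five 9-voxel-per-slice territory blobs on
three slices) with 40 tag/control pairs and a 100 Hz plethysmograph; the
end-to-end check plants the five territory compliances and recovers their
medians within 10% relative at a binned-ΔM SNR of 50. At that SNR the
median's sampling error is ~2% and the remaining systematic ~5% AC
underestimation is the genuine contamination bias (diastolic aBV, being
smaller, is inflated proportionally more than systolic — so AC is biased
low, the direction expected in vivo as well). The phantom's mask
percentile is lowered to 60 in that test because its arterial fraction per
slice (~31%) far exceeds the ~5% of a real brain slice; the in-vivo
default remains 95. Bin-occupancy expectations are estimated with a
uniform random start phase per repetition, since a scanner start is not
locked to the cardiac cycle and a fixed start leaves the first volumes'
phases under-mixed.

## Known limitations

* Compliance transfers brachial pulse pressure to the cerebral arteries;
  intracranial pulse pressure is lower, so AC is likely underestimated — a
  limitation of the measurement principle, not of the implementation.
* The microvascular contamination bias is not corrected, only quantified;
  ROIs restricted to aBV > 1.5 %v keep it below a few percent.
* Peak detection assumes a clean, roughly periodic pulse waveform;
  arrhythmia-robust beat classification and ECG input are out of scope.
* No spatial regularization or partial-volume correction is applied;
  voxels are fitted independently.
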