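# aslcompliance

Cerebral **arterial compliance (AC)** mapping from **short inversion time
pulsed arterial spin labeling (PASL)**.

At inversion times below one second, the PASL tag/control difference signal
is dominated by magnetically labeled blood still inside the large cerebral
arteries (middle, anterior and posterior cerebral arteries), not yet in the
capillary bed. Because arteries distend with every heartbeat, the arterial
blood volume (aBV) of a voxel depends on the cardiac phase at which the
slice was acquired. This package retrospectively sorts multi-TI PASL slices
into cardiac-phase bins using a finger plethysmograph trace, fits a
dispersed plug-flow kinetic model per voxel and phase, and converts the
diastole-to-systole aBV change plus cuff pulse pressure into a compliance
(distensibility) map.

## Model

The macrovascular difference signal of a voxel is

```
ΔM(t) = 2 α (aBV/100) M0a · exp(−t/T1a) · c(t)
c(t)  = ½ [ erf((t−Δt)/(σ√2)) − erf((t−Δt−τ)/(σ√2)) ]
```

where `c(t)` is a square bolus of duration `τ` (fixed at 700 ms by the
QUIPSS II cut-off) convolved with a Gaussian dispersion kernel of width `σ`,
`Δt` is the bolus arrival time, `T1a = 1664 ms` the longitudinal relaxation
time of arterial blood at 3 T, `α` the labeling efficiency and `M0a` the
equilibrium magnetization of arterial blood (calibrated from CSF). The
three free parameters `aBV` (%v), `Δt` (ms) and `σ` (ms) are estimated per
voxel and cardiac-phase bin by bounded Levenberg–Marquardt least squares
over the seven effective inversion times (nominal TI plus 29 ms per
subsequent slice).

Compliance is the normalized aBV change per unit pulse pressure:

```
AC = 100 · (aBV_sys − aBV_dia) / (aBV_dia · PP)      [%/mm Hg]
```

with the early-diastole bin (cardiac phase [1/8, 2/8)) and early-systole
bin ([6/8, 7/8)) of eight half-open phase bins.

## Worked example

No scanner data is needed: the built-in generator simulates a
cardiac-modulated acquisition over a digital phantom with known
ground-truth compliance per territory (planted AC: RMCA 0.57, LMCA 0.50,
ACA 0.43, RPCA 1.1, LPCA 1.1 %/mm Hg).

```r
library(aslcompliance)

spec <- phantom_spec(dim = c(12, 12, 5),
  territories = data.frame(
    name = c("RMCA", "LMCA", "ACA", "RPCA", "LPCA"), label = 1:5,
    cx = c(3, 9, 6, 4, 8), cy = c(7, 7, 10, 3, 3), radius = 1.5,
    abv_dia = c(2.0, 2.2, 1.8, 1.6, 1.68), ac = c(0.57, 0.50, 0.43, 1.1, 1.1),
    dt_dia = c(430, 435, 460, 445, 445), sigma_sys = c(80, 85, 90, 85, 85)),
  territory_slices = 2:4, noise_sd = 0.0012)
timing <- asl_timing(n_pairs = 40, n_slices = 5)
sim <- simulate_acquisition(spec, timing, seed = 7)

res <- run_pipeline(sim$series, sim$physio, sim$bp, sim$truth$labels,
  label_names = setNames(spec$territories$label, spec$territories$name),
  calib = sim$calib, csf_mask = sim$truth$csf_mask,
  percentile = 60, bins = c(2, 7))
print(res)
#> compliance_result (PP = 52.7 mm Hg, m0a = 1)
#>   RMCA   AC =  0.552 %/mmHg  (n = 27 voxels)
#>   LMCA   AC =  0.500 %/mmHg  (n = 27 voxels)
#>   ACA    AC =  0.397 %/mmHg  (n = 27 voxels)
#>   RPCA   AC =  0.977 %/mmHg  (n = 27 voxels)
#>   LPCA   AC =  1.069 %/mmHg  (n = 27 voxels)
```

The recovered territory medians sit within ~10% of the planted values; the
slight underestimation is the expected microvascular contamination bias
(diastolic aBV is inflated a little more than systolic by the perfused
background). That bias can be quantified directly:

```r
simulation_study(c(1.5, 3, 6), dt_tiss_list = 700)
#>   abv_true dt_tiss dt_art abv_fit dt_fit sigma_fit overestimation_pct
#> 1      1.5     700    350    1.53    323      13.2              2.112
#> 2      3.0     700    350    3.03    321      12.4              1.056
#> 3      6.0     700    350    6.03    319      12.1              0.528
```

A thin command-line front end (`inst/cli/aslcompliance`) exposes the same
stages as `simulate`, `run` and `study` subcommands driven by a YAML
config.

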