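# oligotrack

Single-molecule analysis of protein assembly on optically tethered dsDNA
from confocal photon-count images.

In correlative optical-tweezers / confocal experiments, a DNA-binding
protein (the motivating system is the inflammasome sensor AIM2 binding
lambda-phage dsDNA) is imaged as it binds, oligomerizes and detaches on a
single tethered DNA molecule. The raw data are kymographs — photon-count
matrices of position pixels by scan lines — and time-stamped 2D scans.
`oligotrack` is the analysis chain that turns those counts into numbers:

* **Detector dead time** — idealized non-paralyzable correction
  `n = m / (1 - m·tau)` for the APD's 35 ns dead time, applied per pixel.
* **Tracking** — detection and greedy linking of binding events in
  kymographs into traces with sub-pixel positions, photon counts and
  censoring flags.
* **Photobleaching steps** — exact penalized least-squares segmentation of
  intensity staircases on the variance-stabilized scale; the smallest
  downward steps calibrate the unitary single-fluorophore intensity
  (histogram at bin width 3, Gaussian fit).
* **Stoichiometry** — background subtraction, dead-time inversion,
  division by the unitary intensity, red-channel fluorophore equivalents
  (14 red photons = 1 fluorophore for 100-575 blue counts), labeling
  efficiency, and the propagated size error `ΔS = 0.17 S`.
* **Kinetics** — dwell-time histograms (1 s bins, first bin dropped) fit
  to `y = A exp(-k_off t) + y0`; unbound-time bookkeeping and
  `k_on = 1 / ([C]·t_on)`; `K_D = k_off / k_on`.
* **Geometry** — Gaussian profile fits, FWHM-as-diameter areas, DNA
  contour (0.34 nm/bp) and protomer-capacity (10 bp/protomer) rulers.
* **Growth and diffusion** — growth rates as Δcounts/Δt in molecules/s,
  classification of along-DNA (primary) vs perpendicular (secondary)
  growth from intensity-profile trends, and an MSD-based static/diffusive
  verdict per trace.
* **Simulator** — a seeded stochastic generator of kymographs, 2D frame
  sequences, bleaching staircases and dwell sets with full ground truth,
  so every stage above is verifiable without instrument data.

## Worked example

```r
library(oligotrack)

# dead-time correction of a one-fluorophore count rate
model <- dead_time_model(tau_s = 35e-9, window_s = 50e-6)
true_rate(220e3, model)        # 221707 photons/s, i.e. 0.8% undercount

# dissociation kinetics from synthetic single-molecule dwell times
dwells <- simulate_dwell_times(k_off = 0.29, n = 314, seed = 1)
fit <- fit_koff(dwell_histogram(dwells, bin_width_s = 1, drop_first = TRUE))
fit
#> k_off = 0.280 +/- 0.020 s^-1 (R^2 = 0.983, RMSE = 2.30)

# association rate from a bulk assembly rate (irreversible binding)
kon_from_bulk_kobs(0.8, 72e-9, unit = "per_min")   # 1.9e5 /M/s

# affinity range from the fitted k_off and a k_on interval
dissociation_constant(fit$k_off, c(1.81e6, 0.37e6)) * 1e9
#> 155-756 nM

# photons -> molecules with red-channel and labeling corrections
count_molecules(raw_counts = 110, background = 0, red_counts = 14,
                unit = 11, labeling_efficiency = 0.9,
                deadtime = dead_time_model(tau_s = 0))
#> Cluster: 110.0 corrected counts -> 11.00 fluorophores,
#>          12.22 +/- 2.08 molecules
```

The fitted `k_off` of 0.280 ± 0.020 s⁻¹ recovers the generating rate of
0.29 s⁻¹ within its standard error; the cluster example shows 110 blue
photons plus 14 red photons resolving to 11 fluorophores and, at 90%
labeling, 12.2 ± 2.1 molecules.

## Analysis workflow

The `analysis/` scripts run the full study on simulated data, each a thin
narrative driver over the package functions, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R              # datasets + ground truth
Rscript analysis/02_calibrate.R             # unitary intensity, decay rates
Rscript analysis/03_kinetics.R              # k_off, k_on, K_D
Rscript analysis/04_stoichiometry_geometry.R
Rscript analysis/05_growth_diffusion.R
```

The methods vignette (`vignettes/oligotrack-methods.Rmd`) documents the
model, the corrections, the calibrated thresholds and the known
limitations.

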