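---
title: "Methods: single-molecule kymograph analysis of protein-DNA assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule kymograph analysis of protein-DNA assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotrack)
```

# The measurement problem

In a correlative optical-tweezers / confocal experiment, a single
lambda-phage dsDNA molecule (48,502 bp, 0.34 nm/bp, about 16.5 um) is held
between two trapped beads while fluorophore-labeled DNA-binding protein is
introduced. A confocal line scan along the DNA, repeated every few
milliseconds, produces a *kymograph*: a photon-count matrix whose rows are
100 nm position pixels and whose columns are scan lines. Binding events
appear as horizontal streaks; their photon counts encode how many labeled
molecules sit at that position, and their lengths encode residence times.

`oligotrack` turns such photon-count matrices into the quantities a
kinetics study needs: molecule numbers per cluster, dissociation and
association rate constants, cluster geometry, oligomer growth rates and
directions, and a diffusion verdict per trace. Because raw instrument data
of this kind are rarely public, the package carries a first-class
stochastic simulator whose ground truth makes every analysis stage
testable end to end.

# The generative model

`sim_config()` collects every generative parameter; its defaults are the
package's reference conditions:

* **Photon emission.** Each fluorophore emits Poisson photons with mean
  `unit_intensity = 11` per line sample, the unitary intensity of a single
  Alexa-488-class dye under these scan settings (50 us pixel dwell, 10%
  laser power). Photons are spread over pixels by a Gaussian PSF of FWHM
  350 nm integrated across each 100 nm pixel, and a Poisson background is
  added per pixel.
* **Background.** Neither a count rate nor a dark-count figure is fixed by
  the experimental description, so the default `background_rate = 0.2`
  photons/pixel/line was chosen once as typical of photon-counting
  confocal detection with an oxygen-scavenged buffer; at a detection
  threshold of 4 counts per 3-pixel window it produces a realistic but
  manageable false-detection rate.
* **Binding and unbinding.** Events arrive as a Poisson process along the
  tether with uniform positions. Monomers detach at
  `k_off_monomer = 0.29` s^-1; dimers detach at the same rate by default
  (dimers are observed to detach but no separate rate is known; the rate
  is exposed as `dimer_k_off`); clusters reaching
  `permanence_threshold = 3` protomers never detach.
* **Growth.** Clusters gain protomers by two independent Poisson
  mechanisms: *primary* growth (new molecules binding adjacent DNA) places
  each protomer one 10 bp footprint (3.4 nm) further along the DNA on a
  side chosen once per cluster, and *secondary* growth (molecules binding
  the bound cluster directly) stacks protomers perpendicular to the DNA at
  the same spacing. The mechanisms' rates are free parameters because only
  rates, not a mechanistic law, are observable.
* **Photobleaching and labeling.** Each fluorophore carries an exponential
  bleach clock at `bleach_rate = 0.43` s^-1, and each protomer is labeled
  with probability `labeling_efficiency = 0.9`.
* **Detection.** Rendered counts are censored by the idealized dead-time
  model (below) with `dead_time_ns = 35`, applied per pixel as a
  deterministic expected-count thinning rather than event-by-event queuing
  — exactly the model the analysis inverts.
* **Blinking** is deliberately not modeled: no blinking rate is
  experimentally constrained, so the switch exists but refuses to turn on.

What the simulator does *not* emulate: optical sectioning and z-dependent
excitation, polarization and homo-FRET photophysics (the red-channel
correction below is an empirical rule, not physics), bead or trap
mechanics, and DNA fluctuations. Passing tests therefore validate the
*analysis chain* under idealized imaging, not the microscope.

# Detector dead time

A photon-counting APD is blind for `tau` = 35 ns after each event. Under
the idealized non-paralyzable model, a measured rate `m` relates to the
true rate `n` by

$$ n = \frac{m}{1 - m\tau}, $$

so the undercounting fraction is `m * tau`. Counts are converted to rates
over the pixel dwell (50 us), corrected, and converted back
(`correct_counts()`); the correction is applied per pixel, where the
detector actually operates, never to aggregated trace counts.

```{r}
true_rate(220e3)             # one fluorophore: 0.8% undercount
true_rate(2200e3)            # ten fluorophores: 7.7% undercount
```

# Tracking

`track_traces()` detects per-line local maxima of the 3-pixel moving sum
above `min_counts = 4` (about background mean + 3 s.d. for ~1 background
photon per window), assigns sub-pixel positions by intensity centroid over
±2 pixels, and reports per-detection counts as the ±3-pixel window sum
(96% of a 350 nm PSF) minus the estimated background. Detections are
linked greedily to the nearest active trace within `link_radius_px = 2`,
tolerating `max_gap_lines = 3` dark lines (blinking and shot noise); ties
favor higher counts, then lower pixel index. Traces shorter than 2
detected lines are discarded as shot-noise false positives. Traces
touching the first or last scan line are flagged left-/right-censored;
`eligible_dwells()` excludes both from dissociation fits (a trace already
present at the start has an unknown bind time; one running into the end
has a truncated dwell) while both still count toward occupancy for the
unbound-time bookkeeping.

# Photobleaching steps and the unitary intensity

Stepwise photobleaching calibrates the photons-per-fluorophore unit.
`detect_steps()` fits a piecewise-constant model by *exact*
dynamic-programming least-squares segmentation — for any step count the
global optimum over all plateau placements, which is what makes the
exhaustive-enumeration equivalence test possible. Because Poisson noise
scales with the level, the segmentation runs on the variance-stabilized
Anscombe scale `2 * sqrt(y + 3/8)`, where noise is approximately
unit-variance everywhere. Steps are added one at a time and accepted while

1. the transformed residual sum of squares drops by at least `penalty`
   (default `3 * log(n)`, a BIC-like change-point penalty), and
2. every step on the original scale is at least `min_step = 5` photons
   (about half a fluorophore).

A relative "5% variance reduction" rule was evaluated first and rejected:
its threshold collapses on trajectories with long near-zero tails and
over-segments them, while being too conservative elsewhere; the
log-penalty on the stabilized scale behaves uniformly across levels and
trajectory lengths.

`unitary_intensity()` then takes the smallest-magnitude *downward* step of
each trajectory (upward steps are binding or blinking-on events and are
excluded), histograms the magnitudes at bin width 3 with left edges at
zero, and fits a Gaussian to the histogram by least squares. With fewer
than three occupied bins the Gaussian is degenerate and the sample
mean/s.d. are reported instead. The smallest-step selection is slightly
biased low (an order-statistic effect, about half a photon at these
conditions), which is why the recovery tolerance is ±2 counts.

`decay_rate()` fits `I(t) = I0 exp(-k t) + c`. A single 20-fluorophore
staircase carries irreducible lifetime-sampling scatter — the mean of 20
exponential lifetimes has a 22% relative s.d. — so per-cluster rate
estimates straddle the nominal 0.2-0.5 s^-1 band even for a perfect
estimator; the tight rate check therefore uses ensemble-averaged
trajectories.

# Stoichiometry

`count_molecules()` chains the corrections in the order the physics
dictates: subtract the mean background of 3-5 same-aperture regions;
invert the dead time; divide by the unitary intensity to get fluorophores;
add `red_counts / 14` fluorophore-equivalents when the blue counts lie in
[100, 575] (dense clusters shift some emission to red wavelengths, a
constant ~14 photons ~ one fluorophore in that window; above 575 the red
emission grows non-linearly, no correction is defined, and the estimate is
flagged `possibly_underestimated`); divide by the labeling efficiency to
get molecules. The propagated 17% photon-count uncertainty gives the size
error `0.17 * S`. Molecule counts are reported as reals with a
banker's-rounded integer companion.

# Geometry

Cluster sizes on images are diffraction-limited, so apparent geometry uses
the fitted Gaussian FWHM as a circular diameter:
`area_from_fwhm()` / `diameter_from_area()` implement
`A = pi (FWHM/2)^2`. The rulers `dna_contour_length()` (0.34 nm/bp) and
`protomer_capacity()` (one protomer per 10 bp, the crystallographic
footprint) translate base pairs to nanometers and molecule capacities.
The footprint is a parameter because the literature's own capacity figures
imply anywhere from 10 to ~12 bp per protomer; the default keeps the
structural value and the discrepancy is left unresolved.

# Dwell-time kinetics

`dwell_histogram()` bins residence times at 1 s (half-open bins, left
edges at zero) and drops the first bin by default: dwells shorter than the
bin width are depleted by the scan rate and detection threshold, and the
undercounted bin biases the fit. `fit_koff()` fits
`y = A exp(-k_off t) + y0` by unweighted nonlinear least squares
(Levenberg-Marquardt), reporting R² and RMSE. Because binning an
exponential preserves its rate, the fit recovers a closed-form generator
to better than 0.1%.

`unbound_time()` implements the occupancy bookkeeping `t_on = duration -
sum(residence times)`, clamped at zero with an overlap flag — the
estimator's premise is a single binding competence per kymograph, which
many simultaneous traces violate; the flag surfaces exactly that.
`fit_kon()` computes `k_on = 1 / ([C] * mean(t_on))`, and
`kon_from_bulk_kobs()` converts a bulk observed assembly rate to k_on
under the irreversible-binding assumption (valid because clusters of >= 3
are permanent). `dissociation_constant()` is `k_off / k_on`.

Known improvement not implemented by design: censoring-corrected
maximum-likelihood survival fitting would use the right-censored dwells
instead of discarding them; the histogram route is primary here because it
is the method whose outputs the reference values describe.

# Growth and diffusion

`growth_rate()` is the difference between final and initial photon counts
over the observation time, in photons/s and molecules/s;
`measure_cluster_counts()` supplies the counts as background-subtracted
window sums (7x7 pixels by convention for growth; the window is a
parameter) anchored at the brightest point of the time-summed stack.

`classify_direction()` reduces each frame to mean-intensity profiles along
the DNA axis and perpendicular to it (perpendicular profiles are computed
only over the cluster's along-axis window so empty flanks do not dilute
them). Profiles are background-subtracted, clamped at 15% of their peak
(an amplitude-invariant cut that suppresses the noise floor without
biasing widths), and summarized by intensity-weighted centroid and
moment-based FWHM. The first-to-last change of centroid, width and mass is
read off a linear trend over all frames evaluated at the endpoint times —
single first/last frames are shot-noise-limited at realistic intensities,
and the trend estimator measures the same change at roughly three times
the precision. Calibrated thresholds (exposed as arguments): along-axis
centroid shift > 1 pixel, perpendicular FWHM gain > 15%, total intensity
gain > 10% to call any growth; when both signatures fire, a 2x dominance
rule picks the stronger, otherwise the call is "mixed".

`diffusion_stats()` computes the mean squared displacement of a trace's
positions over integer line lags (pairing by line index, so gaps are
handled) and fits a line: slope `2D` for free 1D diffusion, a flat
localization-noise floor for a static molecule. The verdict threshold of
1e4 nm²/s (D = 0.005 um²/s) sits far above the noise-floor slope of
static traces observed with ~0.3 pixel localization noise and far below
the 2e5 nm²/s slope of D = 0.1 um²/s diffusion, giving >= 90% accuracy
both ways at 100-line traces.

# Numerical choices

* Exact segmentation is O(k n²); trajectories analysed here are a few
  hundred to a few thousand lines, for which this costs milliseconds to
  about a second.
* All nonlinear fits use Levenberg-Marquardt with moment-based starting
  values; a start value of exactly zero is nudged off zero because
  relative-step numeric differentiation otherwise produces a zero
  Jacobian column.
* Pixel indices are 0-based with pixel `i` covering `[i, i+1)` in pixel
  units; times are seconds; positions nanometers; concentrations molar.
* Ties in trace linking are broken toward nearest position, then higher
  counts, then lower pixel index; ties in segmentation are resolved by the
  first optimum found, making every routine deterministic.

# Problem sizes used in tests and scripts

The reference experiment scans 10 ms lines for 600 s. The test suite and
analysis scripts keep that line period where it matters (step detection
operates on 10-20 ms sampling) but simulate 12-120 s observations with
arrival rates around 0.4-0.8 events/s, 1-3 fluorophore staircases for
calibration (50-60 per replicate), dwell samples of n = 314 and n = 172
matching the fitted datasets, 10-frame movies at 2 frames/s for growth,
and 100-line traces for diffusion. These sizes were chosen as the smallest
at which the estimators' sampling error is comfortably inside the checked
tolerances.

# Known limitations

* The tracker is greedy nearest-neighbor; crossing traces can swap
  identities. The reference analysis concerns non-diffusing molecules,
  where crossings are rare.
* The k_on estimator inherits the single-competence assumption of the
  unbound-time definition; with many simultaneous traces it undercounts
  available time, and the overlap flag is the only mitigation.
* The red-channel correction is an empirical equivalence, undefined above
  575 blue photons.
* Step counting on trajectories whose plateaus are shorter than a few
  lines is ambiguous (automated detectors report 2 or 3 steps with equal
  fit quality on such data); the fit quality is reported, the ambiguity is
  not adjudicated.
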