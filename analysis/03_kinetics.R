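#!/usr/bin/env Rscript
# Dissociation and association kinetics: exponential fits of the dwell-time
# histograms (1 s bins, first bin dropped), k_on from per-kymograph unbound
# times and from the bulk anisotropy rate, and the K_D range.

suppressPackageStartupMessages(library(oligotrack))
dwells <- read.csv("results/dwell_times.csv")

fits <- lapply(split(dwells, dwells$condition), function(d) {
  fit <- fit_koff(dwell_histogram(d$dwell_s, bin_width_s = 1,
                                  drop_first = TRUE))
  cat(sprintf(
    "%s: k_off %.3f +/- %.3f /s (true %.2f; R^2 %.3f, RMSE %.2f, n = %d)\n",
    d$condition[1], fit$k_off, fit$stderr, d$k_true[1], fit$r_squared,
    fit$rmse, nrow(d)))
  fit
})

# k_on from the tracked kymograph's unbound time at 1 nM
kymo <- read_kymograph("results/kymograph_1nM")
traces <- track_traces(kymo)
t_on <- unbound_time(kymo$total_duration_s, traces)
kon_sm <- fit_kon(t_on$t_on_s, 1e-9)
cat(sprintf("kymograph occupancy: %.1f s bound of %g s -> t_on %.1f s\n",
            t_on$occupied_s, kymo$total_duration_s, t_on$t_on_s))
cat(sprintf("single-molecule k_on at 1 nM: %.3g /M/s\n", kon_sm$k_on))

# bulk-anisotropy k_on under the irreversible-binding assumption
kon_bulk <- kon_from_bulk_kobs(0.8, 72e-9, unit = "per_min")
cat(sprintf("bulk k_on (k_obs 0.8 /min at 72 nM, k_off = 0): %.2g /M/s\n",
            kon_bulk))

# K_D from the measured k_off and the tabulated k_on range
koff <- fits[["17pN"]]$k_off
kd_range <- dissociation_constant(koff, c(1.81e6, 0.37e6))
cat(sprintf("K_D range at k_on 0.37e6-1.81e6: %.0f-%.0f nM\n",
            kd_range[1] * 1e9, kd_range[2] * 1e9))

jsonlite::write_json(
  list(k_off = lapply(fits, function(f) {
         list(k_off = f$k_off, stderr = f$stderr, r_squared = f$r_squared,
              rmse = f$rmse)
       }),
       t_on_s = t_on$t_on_s, k_on_single_molecule = kon_sm$k_on,
       k_on_bulk = kon_bulk, K_D_range_nM = kd_range * 1e9),
  "results/kinetics.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/kinetics.json\n")
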