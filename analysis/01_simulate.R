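#!/usr/bin/env Rscript
# Generate the synthetic datasets every downstream step analyses: a
# kymograph of single-molecule binding events with ground truth, a set of
# photobleaching staircases, and exponential dwell-time samples at the two
# fitted dissociation rates. Everything is seeded, so the whole analysis
# chain is reproducible from this script alone.

suppressPackageStartupMessages(library(oligotrack))
dir.create("results", showWarnings = FALSE)

# Kymograph: lambda-DNA, 50 ms lines for 120 s, ~0.5 binding events/s.
# (The instrument scans 10 ms lines for 600 s; this is a 10x-scaled-down
# rendering of the same physics that keeps the driver fast.)
cfg <- sim_config(arrival_rate = 0.5, duration_s = 120,
                  line_period_s = 0.05, labeling_efficiency = 1, seed = 2024)
sim <- simulate_kymograph(cfg)
write_kymograph(sim$kymograph, "results/kymograph_1nM")
write.csv(sim$truth$events, "results/kymograph_1nM_events.csv",
          row.names = FALSE)
cat(sprintf("kymograph: %d binding events over %g s, %d px x %d lines\n",
            nrow(sim$truth$events), cfg$duration_s,
            nrow(sim$kymograph$counts), ncol(sim$kymograph$counts)))

# Photobleaching staircases for calibration (1-3 fluorophores each)
cal_cfg <- sim_config(line_period_s = 0.02, duration_s = 12,
                      background_rate = 0.2, seed = 2024)
set.seed(2024)
n_fluor <- sample(1:3, 60, replace = TRUE)
stairs <- lapply(seq_along(n_fluor), function(i) {
  simulate_photobleach_trace(n_fluor[i], cal_cfg, seed = 20240 + i)
})
stair_df <- do.call(rbind, lapply(seq_along(stairs), function(i) {
  data.frame(trajectory = i, n_fluor = n_fluor[i],
             line = seq_along(stairs[[i]]$intensity) - 1L,
             counts = stairs[[i]]$intensity)
}))
write.csv(stair_df, "results/bleach_staircases.csv", row.names = FALSE)
cat(sprintf("staircases: %d trajectories, %d true bleach steps\n",
            length(stairs),
            sum(vapply(stairs, function(s) length(s$step_times_s),
                       numeric(1)))))

# Dwell-time samples at the single-molecule rate (n = 314) and the
# 40 pN stretched-DNA rate (n = 172)
dwells <- rbind(
  data.frame(condition = "17pN", k_true = 0.29,
             dwell_s = simulate_dwell_times(0.29, 314, seed = 314)),
  data.frame(condition = "40pN", k_true = 0.52,
             dwell_s = simulate_dwell_times(0.52, 172, seed = 172)))
write.csv(dwells, "results/dwell_times.csv", row.names = FALSE)
cat(sprintf("dwells: %d at 0.29 /s, %d at 0.52 /s; mean dwell %.2f s\n",
            sum(dwells$condition == "17pN"),
            sum(dwells$condition == "40pN"),
            mean(dwells$dwell_s[dwells$condition == "17pN"])))
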