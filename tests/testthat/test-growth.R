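test_that("growth rate is the count difference over the observation time", {
  # 11 -> 35 molecules in 0.85 s, measured as photons with unit 11
  g <- growth_rate(c(0, 0.85), c(11, 35) * 11, unit = 11,
                   labeling_efficiency = 1)
  expect_equal(round(g$rate_molecules_per_s), 28)
  expect_equal(g$rate_photons_per_s, 24 * 11 / 0.85)
  expect_equal(g$start_molecules, 11)
  expect_equal(g$end_molecules, 35)
  flat <- growth_rate(c(0, 1, 2), c(50, 50, 50))
  expect_equal(flat$rate_photons_per_s, 0)
  expect_error(growth_rate(1, 10), "2 time points")
  expect_error(growth_rate(c(1, 1), c(1, 2)), "strictly increasing")
})

test_that("photon and molecule rates agree through the unit intensity", {
  g <- growth_rate(c(0, 2), c(110, 440), unit = 11, labeling_efficiency = 1)
  expect_equal(g$rate_photons_per_s, 11 * g$rate_molecules_per_s)
})

test_that("simulated cluster growth is recovered from frame windows", {
  cfg <- sim_config(bleach_rate = 0, labeling_efficiency = 1,
                    background_rate = 0.2, seed = 1)
  rel_err <- vapply(1:6, function(s) {
    g <- simulate_growth_frames("primary", start_molecules = 5,
                                growth_rate = 10, n_frames = 9,
                                frame_period_s = 0.5, ny = 31, nx = 41,
                                config = cfg, seed = s)
    meas <- measure_cluster_counts(g$frames, g$times_s, window = 11L,
                                   background = cfg$background_rate)
    rec <- growth_rate(meas$time_s, meas$counts, unit = 11,
                       labeling_efficiency = 1)
    truth_rate <- (g$truth$molecules[9] - g$truth$molecules[1]) /
      (g$times_s[9] - g$times_s[1])
    (rec$rate_molecules_per_s - truth_rate) / truth_rate
  }, numeric(1))
  expect_true(all(abs(rel_err) <= 0.25))
})

test_that("growth mechanisms are classified from profile signatures", {
  cfg <- sim_config(bleach_rate = 0, labeling_efficiency = 1,
                    background_rate = 0.2, seed = 1)
  sim_dir <- function(mech, seeds, side = 1) {
    vapply(seeds, function(s) {
      g <- simulate_growth_frames(mech, start_molecules = 10,
                                  growth_rate = 25, n_frames = 10,
                                  frame_period_s = 0.5, ny = 31, nx = 41,
                                  side = side, config = cfg, seed = s)
      classify_direction(g$frames)$direction
    }, character(1))
  }
  primary <- sim_dir("primary", 1:15)
  secondary <- sim_dir("secondary", 1:15)
  expect_gte(mean(primary == "right"), 0.85)
  expect_gte(mean(secondary == "perpendicular"), 0.8)
  expect_gte(mean(c(primary == "right", secondary == "perpendicular")), 0.9)
  left <- sim_dir("primary", 3:6, side = -1)
  expect_true(all(left == "left"))
})

test_that("a ROI outside the frame is rejected and a valid one is honored", {
  cfg <- sim_config(bleach_rate = 0, labeling_efficiency = 1,
                    background_rate = 0.2, seed = 1)
  g <- simulate_growth_frames("primary", start_molecules = 10,
                              growth_rate = 25, n_frames = 10,
                              frame_period_s = 0.5, ny = 31, nx = 41,
                              config = cfg, seed = 2)
  expect_error(classify_direction(g$frames,
                                  roi = list(x0 = 30, y0 = 0, width = 20,
                                             height = 31)),
               "ROI outside")
  d <- classify_direction(g$frames,
                          roi = list(x0 = 5, y0 = 3, width = 31,
                                     height = 25))
  expect_equal(d$direction, "right")
})

test_that("bleaching-only sequences show no growth direction", {
  cfgb <- sim_config(bleach_rate = 0.43, labeling_efficiency = 1,
                     background_rate = 0.2, seed = 1)
  verdicts <- vapply(1:8, function(s) {
    g <- simulate_growth_frames("bleach", start_molecules = 10,
                                growth_rate = 0, n_frames = 10,
                                frame_period_s = 0.5, ny = 31, nx = 41,
                                config = cfgb, seed = s)
    classify_direction(g$frames)$direction
  }, character(1))
  expect_true(all(verdicts == "none"))
})

test_that("mirroring the DNA axis swaps left and right labels only", {
  cfg <- sim_config(bleach_rate = 0, labeling_efficiency = 1,
                    background_rate = 0.2, seed = 1)
  for (s in c(2, 3, 4)) {
    g <- simulate_growth_frames("primary", start_molecules = 10,
                                growth_rate = 25, n_frames = 10,
                                frame_period_s = 0.5, ny = 31, nx = 41,
                                config = cfg, seed = s)
    d1 <- classify_direction(g$frames)
    d2 <- classify_direction(g$frames[, dim(g$frames)[2]:1, ])
    swap <- c(left = "right", right = "left", perpendicular = "perpendicular",
              mixed = "mixed", none = "none")
    expect_equal(d2$direction, unname(swap[d1$direction]))
    expect_equal(d2$centroid_shift_px, -d1$centroid_shift_px,
                 tolerance = 1e-8)
  }
})

test_that("static traces are static and Brownian traces are diffusive", {
  tr0 <- simulate_position_trace(100, d_um2_s = 0, seed = 5)
  expect_equal(diffusion_stats(tr0)$verdict, "static")
  tr1 <- simulate_position_trace(100, d_um2_s = 0.1, seed = 5)
  st <- diffusion_stats(tr1)
  expect_equal(st$verdict, "diffusive")
  expect_gt(st$d_um2_s, 0.05)
  expect_lt(st$d_um2_s, 0.2)
  expect_error(diffusion_stats(simulate_position_trace(10, 0, seed = 1)),
               "too short")
})

test_that("deterministic sub-pixel jitter stays below the noise floor", {
  pos <- rep(c(-0.4, 0.4), 30)
  tr <- oligotrack:::new_trace(
    1L, data.frame(line = 0:59, time_s = (0:59 + 0.5) * 0.01,
                   position_px = pos, counts = 11), 0.01, 61L)
  expect_equal(diffusion_stats(tr)$verdict, "static")
})

test_that("static/diffusive classification is at least 90% accurate", {
  v0 <- vapply(1:100, function(s) {
    diffusion_stats(simulate_position_trace(100, 0, seed = s))$verdict
  }, character(1))
  v1 <- vapply(1:100, function(s) {
    diffusion_stats(simulate_position_trace(100, 0.1, seed = 1000 + s))$verdict
  }, character(1))
  expect_gte(mean(v0 == "static"), 0.9)
  expect_gte(mean(v1 == "diffusive"), 0.9)
})
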