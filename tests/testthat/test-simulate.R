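test_that("dwell-time generator rejects invalid input and is reproducible", {
  expect_error(simulate_dwell_times(0, 10), "positive")
  expect_error(simulate_dwell_times(-1, 10), "positive")
  expect_error(simulate_dwell_times(0.29, 0), "positive integer")
  expect_identical(simulate_dwell_times(0.29, 100, seed = 7),
                   simulate_dwell_times(0.29, 100, seed = 7))
  expect_false(identical(simulate_dwell_times(0.29, 100, seed = 7),
                         simulate_dwell_times(0.29, 100, seed = 8)))
})

test_that("dwell times are exponential with the requested mean", {
  means <- vapply(1:25, function(s) {
    mean(simulate_dwell_times(0.29, 314, seed = s))
  }, numeric(1))
  # closed-form mean 1/0.29 = 3.448 s; Monte-Carlo grand mean over 25 seeds
  expect_equal(mean(means), 1 / 0.29, tolerance = 0.035)
  d <- simulate_dwell_times(1, 1e5, seed = 42)
  ks <- suppressWarnings(stats::ks.test(d, stats::pexp, rate = 1))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("photobleaching staircases start at the unitary level", {
  cfg <- sim_config(line_period_s = 0.05, duration_s = 10,
                    background_rate = 0, seed = 1)
  pre_means <- c()
  for (s in 1:20) {
    tr <- simulate_photobleach_trace(1, cfg, seed = s)
    n_pre <- floor(tr$bleach_times_s[1] / cfg$line_period_s)
    if (n_pre >= 5) {
      pre_means <- c(pre_means, mean(tr$intensity[1:n_pre]))
    }
  }
  expect_gt(length(pre_means), 5)
  expect_equal(mean(pre_means), 11, tolerance = 0.1)
})

test_that("without bleaching the staircase is flat with zero steps", {
  cfg <- sim_config(line_period_s = 0.05, duration_s = 10, bleach_rate = 0,
                    background_rate = 0.2, seed = 3)
  tr <- simulate_photobleach_trace(3, cfg)
  expect_equal(length(tr$step_times_s), 0)
  expect_equal(nrow(detect_steps(tr$intensity)$steps), 0)
  expect_equal(mean(tr$intensity), 33, tolerance = 0.1 * 33)
})

test_that("ensemble-averaged bleaching decays at the configured rate", {
  cfg <- sim_config(line_period_s = 0.05, duration_s = 12,
                    background_rate = 0, seed = 1)
  traj <- vapply(1:40, function(s) {
    simulate_photobleach_trace(10, cfg, seed = 100 + s)$intensity
  }, numeric(240))
  fit <- decay_rate(rowMeans(traj), cfg$line_period_s)
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.43, tolerance = 0.12)
})

test_that("kymograph with no arrivals is background only", {
  cfg <- sim_config(arrival_rate = 0, duration_s = 5, line_period_s = 0.05,
                    seed = 2)
  out <- simulate_kymograph(cfg)
  expect_equal(nrow(out$truth$events), 0)
  # counts are pure Poisson background at 0.2/pixel/line
  n <- length(out$kymograph$counts)
  expect_lt(abs(sum(out$kymograph$counts) - 0.2 * n), 5 * sqrt(0.2 * n))
})

test_that("event arrivals follow the configured Poisson rate", {
  cfg <- sim_config(arrival_rate = 0.5, duration_s = 120,
                    line_period_s = 0.1, dna_length_bp = 5000L, seed = 11)
  out <- simulate_kymograph(cfg)
  expect_lt(abs(nrow(out$truth$events) - 60), 4 * sqrt(60))
})

test_that("emitted photons are conserved between ground truth and image", {
  cfg <- sim_config(arrival_rate = 0.5, duration_s = 30,
                    line_period_s = 0.05, background_rate = 0,
                    dead_time_ns = 0, labeling_efficiency = 1, seed = 5)
  out <- simulate_kymograph(cfg)
  expect_gt(out$truth$total_emitted_photons, 0)
  expect_identical(sum(out$kymograph$counts),
                   as.integer(out$truth$total_emitted_photons))
})

test_that("fixing the seed fixes every output bit-for-bit", {
  cfg <- sim_config(arrival_rate = 0.5, duration_s = 10,
                    line_period_s = 0.05, primary_growth_rate = 0.2, seed = 9)
  a <- simulate_kymograph(cfg)
  b <- simulate_kymograph(cfg)
  expect_identical(a$kymograph$counts, b$kymograph$counts)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$fluorophores, b$truth$fluorophores)
})

test_that("clusters at or above the permanence threshold never unbind", {
  cfg <- sim_config(arrival_rate = 1, duration_s = 60, line_period_s = 0.1,
                    dna_length_bp = 5000L, primary_growth_rate = 0.5,
                    secondary_growth_rate = 0.3, seed = 21)
  ev <- simulate_kymograph(cfg)$truth$events
  big <- ev$max_size >= cfg$permanence_threshold
  expect_gt(sum(big), 3)
  expect_true(all(is.na(ev$unbind_time_s[big])))
})

test_that("ground-truth monomer dwells are exponential at k_off", {
  cfg <- sim_config(arrival_rate = 20, duration_s = 100,
                    line_period_s = 0.1, dna_length_bp = 5000L,
                    bleach_rate = 0, k_off_monomer = 0.29, seed = 13)
  ev <- simulate_kymograph(cfg)$truth$events
  dw <- (ev$unbind_time_s - ev$bind_time_s)[!is.na(ev$unbind_time_s)]
  expect_gt(length(dw), 1000)
  ks <- suppressWarnings(stats::ks.test(dw, stats::pexp, rate = 0.29))
  # alpha = 0.01 Kolmogorov-Smirnov critical value
  expect_lt(unname(ks$statistic), 1.628 / sqrt(length(dw)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(labeling_efficiency = 0), "labeling")
  expect_error(sim_config(labeling_efficiency = 1.2), "labeling")
  expect_error(sim_config(k_off_monomer = -1), "rates")
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(pixel_dwell_us = 500, line_period_s = 0.01),
               "exceeds")
  expect_error(sim_config(blinking = TRUE), "blinking")
})
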