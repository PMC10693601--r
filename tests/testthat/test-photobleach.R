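test_that("a noiseless staircase is recovered exactly", {
  y <- rep(c(33, 22, 11, 0), each = 10)
  fit <- detect_steps(y)
  expect_equal(nrow(fit$steps), 3)
  expect_equal(fit$steps$size, rep(-11, 3))
  expect_equal(fit$steps$sign, rep(-1, 3))
  expect_equal(fit$plateaus$level, c(33, 22, 11, 0))
  expect_equal(fit$plateaus$start_line, c(0, 10, 20, 30))
  expect_equal(fit$rss, 0)
})

test_that("flat trajectories give zero steps and short ones error", {
  expect_equal(nrow(detect_steps(rep(5, 20))$steps), 0)
  set.seed(4)
  expect_equal(nrow(detect_steps(rpois(60, 33))$steps), 0)
  expect_error(detect_steps(c(1, 2, 3)), "at least 4")
})

test_that("step detection is deterministic and idempotent", {
  set.seed(10)
  y <- rep(c(44, 22, 11, 0), each = 15) + rpois(60, 3)
  f1 <- detect_steps(y)
  f2 <- detect_steps(y)
  expect_identical(f1, f2)
  recon <- step_fit_reconstruction(f1)
  f3 <- detect_steps(recon)
  expect_equal(f3$plateaus, f1$plateaus, tolerance = 1e-12)
})

test_that("optimal segmentation matches exhaustive enumeration on short traces", {
  set.seed(99)
  for (case in 1:15) {
    n <- sample(12:30, 1)
    k_true <- sample(0:3, 1)
    bounds <- sort(sample(2:(n - 1), k_true))
    levels <- seq(11 * (k_true + 1), 11, by = -11)
    starts_true <- c(1, bounds)
    lens <- diff(c(starts_true, n + 1))
    y <- rpois(n, rep(levels, lens))
    fit <- detect_steps(y, min_step = 3)
    n_seg <- nrow(fit$plateaus)
    z <- 2 * sqrt(y + 0.375)
    oracle <- exhaustive_segmentation(z, n_seg)
    dp <- oligotrack:::optimal_segmentation(z, n_seg)
    expect_equal(dp$rss, oracle$rss, tolerance = 1e-9)
    expect_equal(dp$starts, oracle$starts)
    expect_equal(fit$plateaus$start_line + 1, oracle$starts)
  }
})

test_that("three-fluorophore staircases yield three steps in most seeds", {
  n_steps <- vapply(1:25, function(s) {
    cfg <- sim_config(line_period_s = 0.01, duration_s = 30,
                      background_rate = 0.2, seed = s)
    tr <- simulate_photobleach_trace(3, cfg)
    nrow(detect_steps(tr$intensity)$steps)
  }, numeric(1))
  expect_gte(mean(n_steps == 3), 0.80)
})

test_that("identical steps give a degenerate but exact calibration", {
  fits <- lapply(1:12, function(i) detect_steps(rep(c(22, 11, 0), each = 8)))
  u <- unitary_intensity(fits)
  expect_equal(u$mean, 11)
  expect_equal(u$sd, 0)
  expect_equal(u$n_steps, 12)
  expect_error(unitary_intensity(fits[1:5]), "at least 10")
})

test_that("unitary intensity is recovered at the true single-fluorophore level", {
  m11 <- vapply(1:5, function(s) calibrate_from_staircases(s)$mean,
                numeric(1))
  expect_true(all(abs(m11 - 11) <= 2))
  m20 <- calibrate_from_staircases(3, unit = 20, min_step = 8)$mean
  expect_equal(m20, 20, tolerance = 0.15)
})

test_that("unitary intensity scales with the trajectory counts", {
  cfg <- sim_config(line_period_s = 0.02, duration_s = 12,
                    background_rate = 0, seed = 1)
  trajs <- lapply(1:40, function(i) {
    simulate_photobleach_trace(sample(1:3, 1), cfg, seed = 500 + i)$intensity
  })
  u1 <- unitary_intensity(lapply(trajs, detect_steps))
  u2 <- unitary_intensity(lapply(trajs, function(y) detect_steps(2 * y)))
  expect_equal(u2$mean / u1$mean, 2, tolerance = 0.1)
})

test_that("upward steps are excluded from calibration", {
  # binding event: step up then bleach down; only the downward step counts
  y <- c(rep(0, 10), rep(25, 10), rep(13, 10))
  fit <- detect_steps(y)
  down <- fit$steps[fit$steps$sign < 0, ]
  expect_equal(nrow(down), 1)
  fits <- c(lapply(1:11, function(i) detect_steps(rep(c(22, 11, 0),
                                                      each = 8))),
            list(fit))
  u <- unitary_intensity(fits)
  expect_equal(u$candidates[12], 12)  # the 25 -> 13 drop, not the rise
})

test_that("decay-rate fitting recovers a closed-form exponential", {
  t <- (1:500 - 0.5) * 0.01
  fit <- decay_rate(100 * exp(-0.43 * t), 0.01)
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.43, tolerance = 1e-4)
  flat <- decay_rate(rep(50, 20), 0.01)
  expect_equal(flat$rate, 0)
  expect_error(decay_rate(c(3, 2, 1), 0.01), "at least 10")
})

test_that("cluster bleaching decay rates fall in the observed range", {
  cfg <- sim_config(line_period_s = 0.02, duration_s = 12,
                    background_rate = 0.2, seed = 1)
  rates <- vapply(1:20, function(s) {
    tr <- simulate_photobleach_trace(20, cfg, seed = 700 + s)
    decay_rate(tr$intensity, cfg$line_period_s)$rate
  }, numeric(1))
  # a 20-fluorophore cluster carries irreducible lifetime-sampling scatter
  # (sd of the mean of 20 exponential lifetimes is ~22%), so individual
  # fits straddle the 0.2-0.5 band; the population centers on 0.43
  expect_gte(mean(rates >= 0.2 & rates <= 0.5), 0.6)
  expect_true(median(rates) >= 0.2 && median(rates) <= 0.5)
  expect_equal(mean(rates), 0.43, tolerance = 0.25)
})
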