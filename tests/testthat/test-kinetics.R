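test_that("dwell histograms drop the undercounted first bin", {
  # 20 short dwells in [0,1) and 294 spread above 1 s
  set.seed(2)
  d <- c(runif(20, 0.05, 0.95), 1 + rexp(294, 0.29))
  h <- dwell_histogram(d, bin_width_s = 1, drop_first = TRUE)
  expect_equal(h$mids[1], 1.5)
  expect_equal(sum(h$counts), 294)
  expect_equal(h$dropped_fraction, 20 / 314)
  expect_true(h$first_bin_dropped)
  h2 <- dwell_histogram(d, drop_first = FALSE)
  expect_equal(sum(h2$counts), 314)
})

test_that("degenerate dwell sets are binned or rejected correctly", {
  h <- dwell_histogram(rep(2.5, 25), drop_first = FALSE)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mids[h$counts > 0], 2.5)
  expect_error(dwell_histogram(numeric(0)), "at least 20")
  expect_error(dwell_histogram(rexp(10, 1)), "at least 20")
  expect_error(dwell_histogram(c(rep(1, 24), -1)), "positive")
})

test_that("exponential fits recover a closed-form generator", {
  t <- seq(0.5, 19.5, by = 1)
  counts <- 120 * exp(-0.29 * t)
  fit <- fit_koff(list(mids = t, counts = counts, bin_width_s = 1,
                       first_bin_dropped = FALSE))
  expect_true(fit$converged)
  expect_lt(abs(fit$k_off - 0.29) / 0.29, 1e-3)
  expect_gt(fit$r_squared, 0.999)
  expect_error(fit_koff(list(mids = 1:3, counts = c(5, 2, 1))),
               "occupied bins")
})

test_that("the dwell pipeline recovers generating rates from finite samples", {
  k1 <- vapply(1:5, function(s) {
    d <- simulate_dwell_times(0.29, 314, seed = s)
    fit_koff(dwell_histogram(d))$k_off
  }, numeric(1))
  expect_equal(mean(k1), 0.29, tolerance = 0.12)
  k2 <- vapply(1:5, function(s) {
    d <- simulate_dwell_times(0.52, 172, seed = s)
    fit_koff(dwell_histogram(d))$k_off
  }, numeric(1))
  expect_equal(mean(k2), 0.52, tolerance = 0.15)
})

test_that("recovered k_off does not depend on protein concentration", {
  # same generator at two nominal concentrations; only sample size differs
  k_1nM <- fit_koff(dwell_histogram(
    simulate_dwell_times(0.29, 100, seed = 41)))$k_off
  k_5nM <- fit_koff(dwell_histogram(
    simulate_dwell_times(0.29, 109, seed = 42)))$k_off
  expect_lt(abs(k_1nM - k_5nM), 0.08)
})

test_that("unbound time is the observation time minus occupancy", {
  expect_equal(unbound_time(600, c(10, 12, 8))$t_on_s, 570)
  expect_equal(unbound_time(600)$t_on_s, 600)
  clamped <- unbound_time(600, c(400, 250))
  expect_equal(clamped$t_on_s, 0)
  expect_true(clamped$overlap)
  tr <- oligotrack:::new_trace(
    1L, data.frame(line = 1:3, time_s = 1:3, position_px = 1, counts = 10),
    1, 10L)
  expect_equal(unbound_time(600, list(tr))$t_on_s, 600 - 3)
})

test_that("k_on follows 1 / (concentration x mean unbound time)", {
  expect_equal(fit_kon(1, 1)$k_on, 1)
  expect_equal(fit_kon(200, 5e-9)$k_on, 1e6)
  est <- fit_kon(c(100, 200, 300), 1e-9)
  expect_equal(est$mean_t_on_s, 200)
  expect_equal(est$k_on, 1 / (1e-9 * 200))
  expect_equal(est$per_kymograph_k_on, 1 / (1e-9 * c(100, 200, 300)))
  expect_error(fit_kon(c(100, -5), 1e-9), "positive")
  expect_error(fit_kon(100, 0), "positive")
})

test_that("k_on is recovered when kymographs hold one binding competence", {
  # the estimator assumes each kymograph's unbound time is the waiting time
  # of a single binding site: generate exactly that renewal structure with
  # a known k_on and check recovery within 25%
  conc <- 1e-9
  k_on_true <- 1e6  # waiting time 1/(k_on C) = 1000 s
  set.seed(55)
  t_ons <- numeric(40)
  for (i in 1:40) {
    wait <- rexp(1, rate = k_on_true * conc)
    dwell <- rexp(1, rate = 0.29)
    t_ons[i] <- unbound_time(wait + dwell, dwell)$t_on_s
  }
  est <- fit_kon(t_ons, conc)
  expect_equal(est$k_on, k_on_true, tolerance = 0.25)
})

test_that("tracked kymograph occupancy feeds the unbound-time bookkeeping", {
  cfg <- sim_config(arrival_rate = 0.05, duration_s = 200,
                    line_period_s = 0.1, labeling_efficiency = 1,
                    dna_length_bp = 5000L, seed = 403)
  out <- simulate_kymograph(cfg)
  traces <- track_traces(out$kymograph)
  t_on <- unbound_time(cfg$duration_s, traces)
  occupied_true <- sum(vapply(seq_len(nrow(out$truth$events)), function(i) {
    ev <- out$truth$events[i, ]
    fl <- out$truth$fluorophores
    b <- fl$bleach_time_s[fl$event_id == ev$event_id]
    if (!length(b)) return(0)
    end <- min(ifelse(is.na(ev$unbind_time_s), cfg$duration_s,
                      ev$unbind_time_s), max(b), cfg$duration_s)
    max(end - ev$bind_time_s, 0)
  }, numeric(1)))
  expect_equal(t_on$occupied_s, occupied_true, tolerance = 0.35)
  expect_equal(t_on$t_on_s, cfg$duration_s - t_on$occupied_s)
})

test_that("bulk observed rates convert to k_on under irreversible binding", {
  expect_equal(kon_from_bulk_kobs(0.8, 72e-9), 0.18e6, tolerance = 0.03)
  expect_equal(kon_from_bulk_kobs(60, 1), 1)
  expect_equal(kon_from_bulk_kobs(1, 1e-6, unit = "per_s"), 1e6)
})

test_that("K_D is the ratio of dissociation to association rates", {
  expect_equal(dissociation_constant(0.29, 1.81e6), 160e-9, tolerance = 0.01)
  expect_equal(dissociation_constant(0.29, 0.37e6), 780e-9, tolerance = 0.01)
  expect_equal(dissociation_constant(1, 1), 1)
  # exact under unit rescaling (nM <-> M)
  kd <- dissociation_constant(0.29, 0.37e6)
  expect_equal(dissociation_constant(0.29 , 0.37e6 * 1e-9) * 1e-9, kd,
               tolerance = 1e-12)
  expect_error(dissociation_constant(0, 1))
  expect_error(dissociation_constant(1, -1))
})

test_that("censored traces are excluded from dwell sets but not occupancy", {
  mk <- function(id, lines, n_total) {
    oligotrack:::new_trace(id, data.frame(line = lines,
                                          time_s = lines + 0.5,
                                          position_px = 1,
                                          counts = 10), 1, n_total)
  }
  traces <- list(mk(1L, 0:3, 20L),    # left-censored
                 mk(2L, 5:8, 20L),    # eligible
                 mk(3L, 16:19, 20L))  # right-censored
  d <- eligible_dwells(traces)
  expect_equal(d, 4)
  expect_equal(unbound_time(20, traces)$occupied_s, 12)
})

test_that("mean eligible dwell approaches 1/k_off", {
  # empirical residence 3.3 s vs 1/0.29 = 3.45 s scale
  d <- simulate_dwell_times(0.29, 5000, seed = 77)
  expect_equal(mean(d), 1 / 0.29, tolerance = 0.05)
})
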