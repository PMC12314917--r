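test_that("rereduction fit recovers analytic decay constants", {
  tr <- synth_p700_decay(k = 0.5, a = 1, t_off = 10, t_end = 40)
  fit <- rereduction_rate(tr, t_off = 10)
  expect_equal(fit$rate, 0.5, tolerance = 0.01 * 0.5)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("rereduction fit tolerates 5% noise within 5% error", {
  set.seed(3)
  for (k_true in c(0.2, 0.8, 2)) {
    tr <- synth_p700_decay(k = k_true, a = 1, t_off = 10,
                           t_end = 10 + 8 / k_true, noise_sd = 0.05)
    fit <- rereduction_rate(tr, t_off = 10)
    expect_lt(abs(fit$rate - k_true) / k_true, 0.05)
  }
})

test_that("non-decaying signals are a fit failure", {
  flat <- p700_trace(seq(0, 20, 0.1), rep(1, 201))
  expect_error(rereduction_rate(flat, t_off = 5), "fit failure")
})

test_that("rate fold changes mirror paired-condition arithmetic", {
  t1 <- synth_p700_decay(k = 0.11, t_off = 5, t_end = 60)
  t2 <- synth_p700_decay(k = 0.01, t_off = 5, t_end = 400)
  r1 <- rereduction_rate(t1, t_off = 5)$rate
  r2 <- rereduction_rate(t2, t_off = 5)$rate
  expect_equal(r1 / r2, 11, tolerance = 0.05)
})

test_that("steady-state oxidation is the light plateau above dark baseline", {
  tt <- seq(0, 120, 0.1)
  sig <- ifelse(tt >= 60 & tt < 120, 1, 0)
  tr <- p700_trace(tt, sig)
  w <- data.frame(t_on = 60, t_off = 120, preceding_dark_start = 0,
                  dark_adaptation_time = 60)
  expect_equal(p700_steady_state(tr, w), 1.0)
  dark <- p700_trace(tt, rep(0.2, length(tt)))
  expect_equal(p700_steady_state(dark, w), 0)
  expect_error(p700_steady_state(tr, data.frame(t_on = 60, t_off = 65,
                                                preceding_dark_start = 0)),
               "shorter")
  # fold changes are invariant to optical scaling
  tr2 <- p700_trace(tt, 3.7 * sig)
  expect_equal(p700_steady_state(tr2, w) / p700_steady_state(tr, w), 3.7)
})

test_that("coanalyze measures constructed lags and flags missing spikes", {
  sim <- dcmu_chopped()
  shifted <- p700_trace(sim$p700$time + 5, sim$p700$signal)
  co <- coanalyze(sim$trace, shifted, sim$windows)
  expect_equal(co$lag[2], 5, tolerance = 0.5)

  flat <- sim$trace
  flat$current <- rep(0, nrow(flat))
  co2 <- coanalyze(flat, sim$p700, sim$windows)
  expect_true(all(co2$flag == "no_spike"))
})

test_that("simulated spike and P700 oxidation are simultaneous", {
  sim <- dcmu_chopped()
  co <- coanalyze(sim$trace, sim$p700, sim$windows)
  expect_true(all(abs(co$lag) < 1))
  expect_true(all(co$simultaneous))
})

test_that("NADPH speeds dark re-reduction and boosts the spike at all
           adaptation times", {
  run <- function(nadph, da) {
    pr <- rbind(light_segment(da, 0, 700), light_segment(60, 50, 700),
                light_segment(30, 0, 700))
    cached(sprintf("p700_n%s_da%d", nadph, da),
           simulate_photocurrent(quiet_config(block_DCMU = 1,
                                              NADPH = nadph), pr))
  }
  for (da in c(10, 60)) {
    s0 <- run(0, da); s1 <- run(1, da)
    f0 <- extract_features(s0$trace, s0$windows)
    f1 <- extract_features(s1$trace, s1$windows)
    expect_gt(f1$spike_charge[1], f0$spike_charge[1])
  }
  s0 <- run(0, 60); s1 <- run(1, 60)
  r0 <- rereduction_rate(s0$p700, t_off = 120, t_end = 150)
  r1 <- rereduction_rate(s1$p700, t_off = 120, t_end = 150)
  expect_gt(r1$rate, r0$rate)

  # spike and steady-state-oxidation fold changes agree within 50%
  f0 <- extract_features(s0$trace, s0$windows)
  f1 <- extract_features(s1$trace, s1$windows)
  spike_fold <- f1$spike_charge[1] / f0$spike_charge[1]
  w <- s0$windows[1, ]
  p_fold <- p700_steady_state(s1$p700, w) / p700_steady_state(s0$p700, w)
  expect_lt(abs(spike_fold - p_fold) / p_fold, 0.5)
})

test_that("zero light yields a flat zero P700 signal once dark-adapted", {
  pr <- light_segment(120, 0, 680)
  p <- simulate_p700(quiet_config(), pr)
  tail_sig <- p$signal[p$time >= 60]
  expect_lt(max(abs(tail_sig)), 0.05)
  expect_lt(diff(range(tail_sig)), 0.01)
})
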