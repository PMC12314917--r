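test_that("dark baseline and noise are recovered, drift-robustly", {
  tr <- analytic_trace()
  db <- dark_baseline(tr, first_window(tr))
  expect_equal(db$level, 1.0, tolerance = 1e-9)
  expect_equal(db$noise_sigma, 0, tolerance = 1e-9)

  trn <- analytic_trace(noise_sd = 0.05, off = 60)
  dbn <- dark_baseline(trn, first_window(trn))
  expect_lt(abs(dbn$noise_sigma - 0.05) / 0.05, 0.2)

  # linear drift does not inflate the detrended noise estimate
  trd <- analytic_trace(noise_sd = 0.05, drift = 0.01)
  dbd <- dark_baseline(trd, first_window(trd))
  expect_lt(abs(dbd$noise_sigma - 0.05) / 0.05, 0.2)

  short <- ts_trace(seq(0, 10, 0.1), rep(1, 101),
                    stimulus = c(rep(0, 20), rep(50, 81)))
  expect_error(dark_baseline(short, list(preceding_dark_start = 0, t_on = 2)),
               "shorter than 4 s")
})

test_that("steady-state photocurrent is the plateau difference and is
           invariant under linear drift", {
  tr <- analytic_trace(dark_level = 1, delta_ss = 0.5)
  w <- first_window(tr)
  ss <- steady_state_photocurrent(tr, w)
  expect_equal(ss$steady_state, 0.5, tolerance = 1e-3)

  trd <- analytic_trace(dark_level = 1, delta_ss = 0.5, drift = 0.1 / 60)
  wd <- first_window(trd)
  wins <- detect_photoperiods(trd, "stimulus")
  ssd <- steady_state_photocurrent(trd, wd, following = NULL)
  expect_equal(ssd$steady_state, 0.5, tolerance = 0.01)

  dark <- ts_trace(seq(0, 100, 0.1), rep(1, 1001),
                   stimulus = rep(0, 1001))
  expect_equal(nrow(detect_photoperiods(dark, "stimulus")), 0L)
})

test_that("spike charge matches the analytic exponential integral", {
  tr <- analytic_trace(A = 2, tau = 3, delta_ss = 0.5)
  w <- first_window(tr)
  lt <- thylakem:::light_tail(tr, w)
  sp <- spike_charge(tr, w, light_level = lt$level, noise_sigma = 0)
  expect_equal(sp$charge, 6.0, tolerance = 0.02 * 6)
})

test_that("monophasic profiles yield zero spike charge", {
  tr <- analytic_trace(A = 0, delta_ss = 0.5, noise_sd = 0.01)
  w <- first_window(tr)
  db <- dark_baseline(tr, w)
  sp <- spike_charge(tr, w, noise_sigma = db$noise_sigma)
  # integrand never exceeds 3 sigma for long: charge is a small residual
  expect_lt(sp$charge, 0.05)
})

test_that("spike charge is invariant to offsets and scales with current", {
  tr <- analytic_trace()
  w <- first_window(tr)
  base <- spike_charge(tr, w, noise_sigma = 0)$charge
  shifted <- tr; shifted$current <- shifted$current + 5
  expect_equal(spike_charge(shifted, w, noise_sigma = 0)$charge, base,
               tolerance = 1e-9)
  scaled <- tr; scaled$current <- scaled$current * 3
  expect_equal(spike_charge(scaled, w, noise_sigma = 0)$charge, 3 * base,
               tolerance = 1e-9)
})

test_that("extract_features isolates per-window failures", {
  tr <- analytic_trace(cycles = 2)
  wins <- detect_photoperiods(tr, "stimulus")
  # corrupt first window: dark segment too short
  wins$preceding_dark_start[1] <- wins$t_on[1] - 1
  ft <- extract_features(tr, wins)
  expect_equal(nrow(ft), 2L)
  expect_true(grepl("error", ft$flag[1]))
  expect_true(is.na(ft$spike_charge[1]))
  expect_false(is.na(ft$spike_charge[2]))

  expect_equal(nrow(extract_features(tr, wins[0, ])), 0L)
})

test_that("relative change reproduces inhibition percentages", {
  expect_equal(relative_change(0.07, 1.00), -93)
  expect_equal(relative_change(0.26, 1.00), -74)
  expect_equal(relative_change(1, 1), 0)
  expect_warning(out <- relative_change(1, 0), "zero control")
  expect_true(is.na(out))
})

test_that("replicate aggregation gives mean, sem and Welch p-values", {
  g <- aggregate_replicates(c(0.9, 1.0, 1.1))
  expect_equal(g$mean, 1.0)
  expect_equal(g$sem, sd(c(0.9, 1.0, 1.1)) / sqrt(3))
  expect_equal(g$sem, 0.0577, tolerance = 1e-3)

  same <- aggregate_replicates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  degen <- aggregate_replicates(c(1, 1, 1), c(2, 2, 2))
  expect_true(grepl("degenerate_variance", degen$flag))
  expect_equal(degen$relative_change_pct, -50)

  single <- aggregate_replicates(1.5, c(1, 2))
  expect_true(is.na(single$sem))
  expect_true(grepl("sem_unavailable", single$flag))

  welch <- aggregate_replicates(c(1.0, 1.1, 0.9), c(2.0, 2.2, 1.8))
  expect_equal(welch$p_value,
               t.test(c(1.0, 1.1, 0.9), c(2.0, 2.2, 1.8))$p.value)
})
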