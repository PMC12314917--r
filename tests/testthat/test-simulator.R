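test_that("default chopped-light run shows spike and steady state", {
  sim <- default_chopped()
  ft <- extract_features(sim$trace, sim$windows)
  expect_true(all(ft$spike_charge > 0))
  expect_true(all(ft$steady_state_photocurrent > 0))
  # spike relaxes back towards the plateau well before light-off
  expect_true(all(ft$spike_window_end < sim$windows$t_off - 30))
})

test_that("DCMU suppresses the steady state but not the spike", {
  f0 <- extract_features(default_chopped()$trace,
                         default_chopped()$windows)
  fD <- extract_features(dcmu_chopped()$trace, dcmu_chopped()$windows)
  expect_lt(fD$steady_state_photocurrent[2],
            0.1 * f0$steady_state_photocurrent[2])
  expect_lt(abs(fD$spike_charge[2] - f0$spike_charge[2]) /
              f0$spike_charge[2], 0.1)
})

test_that("spike charge grows with dark adaptation up to saturation", {
  spikes <- sapply(c(10, 60, 300), function(da) {
    pr <- rbind(light_segment(da, 0, 700), light_segment(60, 50, 700),
                light_segment(20, 0, 700))
    s <- cached(sprintf("da_%d", da),
                simulate_photocurrent(quiet_config(block_DCMU = 1), pr))
    extract_features(s$trace, s$windows)$spike_charge[1]
  })
  expect_true(all(diff(spikes) > 0))
  # saturating: the 60->300 s gain is much smaller than the 10->60 s gain
  expect_lt(spikes[3] - spikes[2], 0.3 * (spikes[2] - spikes[1]))
})

test_that("per-pathway ledger sums to the integral of the noiseless
           current under the same quadrature", {
  for (sim in list(default_chopped(), dcmu_wt_staircase())) {
    lhs <- sum(sim$ledger)
    rhs <- thylakem:::trapz(sim$trace$time, sim$clean_current)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("electrons are conserved to integrator accuracy", {
  set.seed(5)
  for (rep in 1:5) {
    cfg <- quiet_config(block_DCMU = sample(0:1, 1),
                        NADPH = runif(1, 0, 1),
                        E_app = sample(seq(-100, 500, 100), 1),
                        mediator_present = sample(c(TRUE, FALSE), 1))
    sim <- simulate_photocurrent(cfg, chopped_light_protocol(1))
    co <- sim$conservation
    resid <- co$injected - co$electrode - co$oxidase - co$recombination -
      co$pool_change
    expect_lt(abs(resid) / max(co$injected, 1), 1e-8)
  }
})

test_that("pathway gating is monotone in applied potential", {
  cfg <- quiet_config(mediator_present = TRUE)
  path <- thylakem:::pathway_params(cfg)
  y <- c(r_PQ = 0.7, r_Pc = 0.6, r_P700 = 0.5, r_A = 0.6)
  Es <- seq(-800, 800, 50)
  jmat <- sapply(Es, function(E) {
    forc <- list(E = E, L = 1, wII = 1, wI = 1)
    thylakem:::chain_fluxes(y, cfg, path, forc)$j
  })
  for (p in rownames(jmat)) {
    expect_true(all(diff(jmat[p, ]) >= -1e-12), info = p)
  }
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- etc_config(noise_sigma = 0.05, seed = 123L)
  a <- simulate_photocurrent(cfg, chopped_light_protocol(1))
  b <- simulate_photocurrent(cfg, chopped_light_protocol(1))
  expect_identical(a$trace$current, b$trace$current)
  expect_identical(a$ledger, b$ledger)

  cfg2 <- etc_config(noise_sigma = 0.05, seed = 124L)
  c2 <- simulate_photocurrent(cfg2, chopped_light_protocol(1))
  expect_identical(a$clean_current, c2$clean_current)
  expect_false(identical(a$trace$current, c2$trace$current))
})

test_that("wavelength weights implement PSI-selective excitation", {
  # 730 nm drives PSI strongly but PSII barely: steady state collapses
  # while dark-accumulated spikes persist
  s680 <- default_chopped()
  pr <- chopped_light_protocol(2, wavelength = 730)
  s730 <- cached("chop_730", simulate_photocurrent(quiet_config(), pr))
  f680 <- extract_features(s680$trace, s680$windows)
  f730 <- extract_features(s730$trace, s730$windows)
  expect_lt(f730$steady_state_photocurrent[2],
            0.2 * f680$steady_state_photocurrent[2])
  expect_gt(f730$spike_charge[2], 0.5 * f680$spike_charge[2])
})

test_that("ferricyanide shuttle enhances the steady state above +500 mV", {
  base <- scan_of(default_staircase())
  med <- scan_of(cached("stair_med_o2",
                        simulate_stepped_ca(quiet_config(
                          mediator_present = TRUE))))
  sel <- base$E_app >= 500
  expect_true(all(med$steady_state_photocurrent[sel] >
                    base$steady_state_photocurrent[sel]))
})

test_that("HQNO reduces the steady state and leaves a clear spike", {
  sH <- cached("chop_hqno",
               simulate_photocurrent(quiet_config(block_HQNO = 1),
                                     chopped_light_protocol(2)))
  f0 <- extract_features(default_chopped()$trace,
                         default_chopped()$windows)
  fH <- extract_features(sH$trace, sH$windows)
  expect_lt(fH$steady_state_photocurrent[2],
            f0$steady_state_photocurrent[2])
  expect_gt(fH$spike_charge[2], 0.2 * f0$spike_charge[2])
})

test_that("invalid configurations are rejected", {
  expect_error(etc_config(block_DCMU = 2), "block_DCMU")
  expect_error(etc_config(strain = "unknown"), "strain")
  expect_error(etc_config(nonsense = 1), "unknown")
})
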