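make_scan <- function(E, ss = NA, sp = NA, sigma = 0.01) {
  n <- length(E)
  structure(data.frame(E_app = E,
                       spike_charge = rep_len(sp, n),
                       steady_state_photocurrent = rep_len(ss, n),
                       noise_sigma = rep(sigma, n),
                       n_photoperiods = 1L, flag = NA_character_),
            class = c("potential_scan", "data.frame"))
}

test_that("onset potential follows the first persistent exceedance", {
  sc <- make_scan(seq(-300, 200, 100), ss = c(0, 0, 0, 0.2, 0.5, 0.5))
  expect_equal(onset_potential(sc, "steady_state"), 0)
  expect_true(is.na(onset_potential(make_scan(seq(-300, 200, 100),
                                              ss = rep(0, 6)),
                                    "steady_state")))
  # a single-row blip below the persistent run is not the onset
  sc2 <- make_scan(seq(-400, 100, 100), ss = c(0, 0.2, 0, 0.3, 0.5, 0.5))
  expect_equal(onset_potential(sc2, "steady_state"), -100)
})

test_that("onset potential is monotone in the threshold multiplier k", {
  set.seed(11)
  for (rep in 1:20) {
    v <- cumsum(abs(rnorm(8, 0.2, 0.2)))
    sc <- make_scan(seq(-400, 300, 100), ss = v, sigma = runif(1, 0.01, 0.3))
    onsets <- sapply(c(1, 3, 6, 12), function(k)
      onset_potential(sc, "steady_state", k = k))
    onsets <- onsets[!is.na(onsets)]
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("feature maximum potential returns the first row near maximum", {
  sc <- make_scan(seq(-100, 300, 100), ss = c(0, 0.3, 0.5, 0.5, 0.5))
  expect_equal(feature_maximum_potential(sc, "steady_state"), 100)
  inc <- make_scan(seq(-100, 300, 100), ss = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(feature_maximum_potential(inc, "steady_state"), 300)
  expect_error(feature_maximum_potential(
    make_scan(seq(-100, 100, 100), ss = rep(0, 3)), "steady_state"),
    "flat zero")
})

test_that("decay onset finds the persistent fall below the plateau", {
  sc <- make_scan(seq(-100, 300, 100), sp = c(1.0, 1.0, 0.95, 0.6, 0.3))
  expect_equal(decay_onset(sc), 200)
  up <- make_scan(seq(-100, 300, 100), sp = c(1.0, 1.0, 1.0, 1.05, 1.1))
  expect_true(is.na(decay_onset(up)))
  ramp <- make_scan(seq(-100, 300, 100), sp = c(0.1, 0.5, 1.0, 1.5, 2.0))
  expect_error(decay_onset(ramp), "plateau")
})

test_that("features_vs_potential sorts rows and flags empty steps", {
  sim <- cached("stair_small",
                simulate_stepped_ca(quiet_config(),
                                    potentials = c(100, -100, 0),
                                    dark = 30, on = 30))
  sc <- features_vs_potential(sim$trace, detect_potential_steps(sim$trace))
  expect_equal(sc$E_app, c(-100, 0, 100))
  expect_true(all(is.finite(sc$steady_state_photocurrent)))

  # single-step trace equals extract_features output
  sim1 <- cached("stair_one",
                 simulate_stepped_ca(quiet_config(), potentials = 300,
                                     dark = 30, on = 30))
  sc1 <- features_vs_potential(sim1$trace,
                               detect_potential_steps(sim1$trace))
  ft <- extract_features(sim1$trace, detect_photoperiods(sim1$trace,
                                                         "stimulus"))
  expect_equal(nrow(sc1), 1L)
  expect_equal(sc1$spike_charge, mean(ft$spike_charge), tolerance = 1e-9)
})

test_that("mediator shifts the spike-charge onset negative, never positive", {
  plain <- scan_of(default_staircase())
  med <- scan_of(mediated_staircase())
  o_plain <- onset_potential(plain, "spike_charge")
  o_med <- onset_potential(med, "spike_charge")
  expect_lte(o_med, o_plain)
})

test_that("oxidase knockout shifts the spike decay to more positive
           potentials", {
  wt <- decay_onset(scan_of(dcmu_wt_staircase()))
  mut <- decay_onset(scan_of(dcmu_mutant_staircase()))
  expect_gt(mut, wt)
})
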