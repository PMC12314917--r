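test_that("baseline correction removes linear capacitive backgrounds", {
  vg <- simulate_cv(quiet_config(), couples = character(0))
  bc <- baseline_correct(vg, exclusion = c(0, 150))
  expect_lt(max(abs(bc$current)), 1e-6)

  zero <- voltammogram(c(0:10, 10:0), rep(0, 22), scan_rate = 10)
  bz <- baseline_correct(zero, exclusion = c(3, 6))
  expect_equal(bz$current, rep(0, 22))
})

test_that("peak shapes survive baseline correction within 1%", {
  cfg_pure <- quiet_config()
  cfg_pure$cv$capacitance <- 0
  cfg_pure$cv$cap_slope <- 0
  ref <- simulate_cv(cfg_pure, couples = "quinone")  # peak-only oracle
  withbg <- simulate_cv(quiet_config(), couples = "quinone")
  bc <- baseline_correct(withbg, exclusion = c(-80, 230))
  pk_ref <- find_redox_peaks(ref)
  pk_bc <- find_redox_peaks(bc)
  expect_equal(pk_bc$E_pa, pk_ref$E_pa, tolerance = 1)
  expect_equal(pk_bc$i_pa, pk_ref$i_pa, tolerance = 0.01 * pk_ref$i_pa)
  expect_equal(pk_bc$i_pc, pk_ref$i_pc, tolerance = 0.01 * abs(pk_ref$i_pc))
})

test_that("midpoint is the mean of symmetric peaks", {
  E <- c(seq(-100, 300, 1), seq(300, -100, -1))
  an <- exp(-((E - 104) / 30)^2)
  ca <- -exp(-((E - 50) / 30)^2)
  dirn <- c(rep(1, 401), rep(-1, 401))
  i <- ifelse(dirn > 0, an, ca)
  vg <- voltammogram(E, i, scan_rate = 10)
  pk <- find_redox_peaks(vg)
  expect_equal(pk$E_pa, 104)
  expect_equal(pk$E_pc, 50)
  expect_equal(pk$E_m, 77)
})

test_that("midpoint estimates are invariant to scaling and linear baseline", {
  vg <- simulate_cv(quiet_config(), couples = "quinone")
  bc <- baseline_correct(vg, exclusion = c(-80, 230))
  em0 <- find_redox_peaks(bc)$E_m
  scaled <- bc; scaled$current <- scaled$current * 7
  expect_equal(find_redox_peaks(scaled)$E_m, em0)
  tilted <- vg; tilted$current <- tilted$current + 0.002 * tilted$potential
  em2 <- find_redox_peaks(baseline_correct(tilted,
                                           exclusion = c(-80, 230)))$E_m
  expect_equal(em2, em0, tolerance = 2)
})

test_that("simulated couples recover their tabulated midpoints", {
  tab <- cofactor_table()
  vg <- simulate_cv(quiet_config(), vertices = c(-200, 600), rate = 10)
  pk <- find_redox_peaks(baseline_correct(vg, exclusion = c(-80, 230)))
  expect_equal(pk$E_m, tab$E_m[tab$name == "pq_pool"], tolerance = 5)

  vg2 <- simulate_cv(quiet_config(mediator_present = TRUE),
                     vertices = c(100, 700), rate = 10,
                     couples = "mediator")
  pk2 <- find_redox_peaks(baseline_correct(vg2, exclusion = c(290, 550)))
  expect_equal(pk2$E_m, tab$E_m[tab$name == "mediator_couple"],
               tolerance = 5)
})

test_that("surface-couple peak separation vanishes in the slow-scan limit", {
  seps <- sapply(c(50, 10, 1), function(nu) {
    vg <- simulate_cv(quiet_config(), rate = nu, couples = "quinone")
    find_redox_peaks(baseline_correct(vg, exclusion = c(-80, 230)))$
      peak_separation
  })
  expect_true(all(diff(seps) <= 0))
  expect_lt(seps[3], 2)
})

test_that("degenerate voltammograms raise informative errors", {
  vg <- simulate_cv(quiet_config(), couples = character(0))
  bc <- baseline_correct(vg, exclusion = c(0, 150))
  expect_error(find_redox_peaks(bc), "no couple")
  expect_error(simulate_cv(quiet_config(), rate = 0), "scan rate")
  expect_error(baseline_correct(vg, exclusion = c(-300, 700)),
               "inside the scanned range")
  expect_error(baseline_correct(vg, exclusion = c(-195, 595)), "80%")
})
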