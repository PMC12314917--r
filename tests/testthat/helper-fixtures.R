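# Shared fixtures. Simulations are cached per test run so expensive scans
# are integrated once and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

quiet_config <- function(...) etc_config(noise_sigma = 0, drift = 0, ...)

scan_of <- function(sim) {
  steps <- detect_potential_steps(sim$trace)
  features_vs_potential(sim$trace, steps)
}

# staircases used by several files
default_staircase <- function() {
  cached("stair_default", simulate_stepped_ca(quiet_config()))
}
dcmu_wt_staircase <- function() {
  cached("stair_dcmu_wt",
         simulate_stepped_ca(quiet_config(block_DCMU = 1),
                             potentials = seq(-100, 700, 100)))
}
dcmu_mutant_staircase <- function() {
  cached("stair_dcmu_mut",
         simulate_stepped_ca(quiet_config(block_DCMU = 1,
                                          strain = "dCydCoxArto"),
                             potentials = seq(-100, 700, 100)))
}
mediated_staircase <- function() {
  cached("stair_mediated",
         simulate_stepped_ca(quiet_config(mediator_present = TRUE,
                                          oxygen_removed = TRUE)))
}
default_chopped <- function() {
  cached("chop_default",
         simulate_photocurrent(quiet_config(), chopped_light_protocol(2)))
}
dcmu_chopped <- function() {
  cached("chop_dcmu",
         simulate_photocurrent(quiet_config(block_DCMU = 1),
                               chopped_light_protocol(2)))
}

# analytic chronoamperometry trace: dark level, then per photoperiod an
# exponential spike of amplitude A and time constant tau on a plateau
# delta_ss above dark
analytic_trace <- function(dark_level = 1, delta_ss = 0.5, A = 2, tau = 3,
                           on = 60, off = 60, cycles = 1, dt = 0.1,
                           drift = 0, noise_sd = 0, seed = 42) {
  tt <- seq(0, cycles * (on + off) + off, by = dt)
  i <- rep(dark_level, length(tt))
  stim <- numeric(length(tt))
  for (k in seq_len(cycles)) {
    t_on <- off + (k - 1) * (on + off)
    lit <- tt >= t_on & tt < t_on + on
    i[lit] <- dark_level + delta_ss + A * exp(-(tt[lit] - t_on) / tau)
    stim[lit] <- 50
  }
  i <- i + drift * tt
  if (noise_sd > 0) {
    set.seed(seed)
    i <- i + rnorm(length(i), sd = noise_sd)
  }
  ts_trace(tt, i, stimulus = stim,
           metadata = experiment_metadata(E_app = 300))
}

first_window <- function(trace) detect_photoperiods(trace, "stimulus")[1, ]
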