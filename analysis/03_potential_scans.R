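#!/usr/bin/env Rscript
# Potential-resolved pathway assignment: stepped chronoamperometry scans
# under four configurations, reduced to feature-vs-E_app tables and the
# derived onset, maximum and decay potentials that identify which membrane
# cofactor exchanges electrons with the electrode at which applied
# potential.

suppressMessages(library(thylakem))
dir.create("results", showWarnings = FALSE)

scan_of <- function(sim) {
  features_vs_potential(sim$trace, detect_potential_steps(sim$trace))
}
cfg <- function(...) etc_config(noise_sigma = 0, ...)

scans <- list(
  default = scan_of(simulate_stepped_ca(cfg())),
  mediated_anoxic = scan_of(simulate_stepped_ca(
    cfg(mediator_present = TRUE, oxygen_removed = TRUE))),
  dcmu_wt = scan_of(simulate_stepped_ca(cfg(block_DCMU = 1),
                                        potentials = seq(-100, 700, 100))),
  dcmu_oxidase_ko = scan_of(simulate_stepped_ca(
    cfg(block_DCMU = 1, strain = "dCydCoxArto"),
    potentials = seq(-100, 700, 100)))
)

tab <- do.call(rbind, lapply(names(scans), function(nm) {
  cbind(condition = nm, as.data.frame(scans[[nm]]))
}))
write.csv(tab, "results/potential_scans.csv", row.names = FALSE)

derived <- list(
  default = list(
    onset_steady_state = onset_potential(scans$default, "steady_state"),
    maximum_steady_state = feature_maximum_potential(scans$default,
                                                     "steady_state"),
    onset_spike = onset_potential(scans$default, "spike_charge")),
  mediated_anoxic = list(
    onset_spike = onset_potential(scans$mediated_anoxic, "spike_charge")),
  dcmu_wt = list(decay_onset_spike = decay_onset(scans$dcmu_wt)),
  dcmu_oxidase_ko = list(
    decay_onset_spike = decay_onset(scans$dcmu_oxidase_ko))
)
jsonlite::write_json(derived, "results/derived_potentials.json",
                     auto_unbox = TRUE, digits = NA)

cat("Steady-state photocurrent appears at",
    derived$default$onset_steady_state, "mV and peaks by",
    derived$default$maximum_steady_state, "mV vs SHE.\n")
cat("With a soluble mediator and oxygen removed, the spike persists down to",
    derived$mediated_anoxic$onset_spike, "mV vs SHE (PSI acceptor side).\n")
cat("Spike decay starts at", derived$dcmu_wt$decay_onset_spike,
    "mV (wild type) vs", derived$dcmu_oxidase_ko$decay_onset_spike,
    "mV (oxidase knockout): the oxidase relay drains the dark store first.\n")
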