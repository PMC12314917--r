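#!/usr/bin/env Rscript
# Generate the synthetic study set: chopped-light photocurrent recordings
# of thylakoid-membrane electrodes under the conditions the downstream
# analyses compare — a solvent control, PSII and cytochrome b6f inhibition
# (DCMU, HQNO), PSI-selective far-red illumination, dehydrogenase substrate
# (NADPH), and the terminal-oxidase knockout strain. Three replicate seeds
# per condition, 60 s on / 60 s off at 50 umol photons m-2 s-1, E_app
# +300 mV vs SHE, with the default measurement-noise model.

suppressMessages(library(thylakem))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

conditions <- list(
  control = list(),
  dcmu = list(block_DCMU = 1),
  hqno = list(block_HQNO = 1),
  farred730 = list(),          # wavelength set in the protocol below
  nadph = list(NADPH = 1),
  oxidase_ko = list(strain = "dCydCoxArto")
)

for (cond in names(conditions)) {
  wavelength <- if (cond == "farred730") 730 else 680
  protocol <- chopped_light_protocol(n_cycles = 3, wavelength = wavelength)
  for (seed in 1:3) {
    cfg <- do.call(etc_config, c(conditions[[cond]], list(seed = seed)))
    run_simulation(cfg, protocol, out_dir = out,
                   name = sprintf("%s_rep%d", cond, seed))
  }
  cat(sprintf("simulated %s (3 replicates, %d nm)\n", cond, wavelength))
}

cat("wrote traces, ledgers and config echoes under", out, "\n")
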