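#' Default cofactor / interfacial-pathway table
#'
#' One row per interfacial electron-transfer route between the membrane and
#' the electrode. `E_gate` is the applied potential (mV vs SHE) at which the
#' route is half-activated; gating is Nernstian with width `gate_width`
#' (mV). `E_m` is the thermodynamic midpoint of the underlying couple where
#' one is resolved by voltammetry (the membrane quinone pool and the
#' soluble ferri/ferrocyanide mediator); for the quinone pool the electrode
#' route activates only at a large overpotential above its midpoint, which
#' is why `E_gate` and `E_m` differ. `mode` distinguishes routes that
#' divert a share of the instantaneous chain flux (`"diversion"`) from
#' routes that oxidise a standing pool down to its potential-dependent
#' equilibrium (`"pool"`); `k_et` is the diverted fraction cap for the
#' former and the maximal exchange current (uA) for the latter.
#'
#' @return A data frame with columns `name`, `pathway_class`, `E_m`,
#'   `E_gate`, `n_electrons`, `gate_width`, `k_et`, `mode`, `requires`.
#' @export
cofactor_table <- function() {
  tab <- data.frame(
    name = c("psii_qb", "cytb6f_cn", "psi_acceptor", "psi_acceptor_med",
             "oxidase_relay", "pq_pool", "mediator_couple"),
    pathway_class = c("PSII-acceptor-side", "cytb6f", "PSI-acceptor-direct",
                      "PSI-acceptor-mediated", "oxidase-relay",
                      "PQH2-direct", "mediator-couple"),
    E_m = c(NA, NA, NA, NA, NA, 77, 420),
    E_gate = c(-100, 100, -100, -600, 150, 250, 420),
    n_electrons = c(2, 1, 1, 1, 2, 2, 1),
    gate_width = c(30, 30, 30, 30, 30, 30, 30),
    k_et = c(0.65, 0.5, 1.7, 16.0, 0.105, 0.105, 0.3),
    mode = c("diversion", "diversion", "pool", "pool", "pool", "pool",
             "diversion"),
    requires = c("", "", "", "mediator", "oxidase", "", "mediator"),
    stringsAsFactors = FALSE)
  stopifnot(all(tab$gate_width > 0))
  tab
}

#' Oxidising gate: equilibrium oxidised fraction at the electrode
#'
#' `gate(E) = 1 / (1 + exp(-(E - E_gate) / w))`, the Nernst-shaped fraction
#' of a surface couple the electrode holds oxidised at applied potential
#' `E`. Monotone non-decreasing in `E`.
#'
#' @param E applied potential, mV vs SHE.
#' @param E_gate half-activation potential, mV vs SHE.
#' @param w gate width, mV (> 0).
#' @return Value in (0, 1).
#' @export
gate_fraction <- function(E, E_gate, w = 30) stats::plogis((E - E_gate) / w)

#' Configuration of the thylakoid-membrane electron-transport model
#'
#' Assembles the full parameter set of the kinetic simulator: redox-pool
#' capacities, chain rate constants, the interfacial pathway table,
#' inhibitor blocks, substrate levels, strain and oxygen flags, applied
#' potential, the flux-to-current scaling, and the noise model. All pool
#' capacities are in microcoulombs of electron charge and all rates in
#' uC/s, so fluxes read directly as microamperes.
#'
#' The defaults encode the study conditions of the experiments the
#' simulator emulates: 680 nm chopped light at 50 umol photons m^-2 s^-1,
#' E_app = +300 mV vs SHE, wild-type membranes with residual oxygen, no
#' exogenous mediator, gates calibrated so the pathway onsets sit at the
#' potentials resolved by stepped chronoamperometry (-100, +100, +200,
#' +300, -600 mV vs SHE).
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `etc_config`.
#' @export
etc_config <- function(...) {
  cfg <- list(
    # pool capacities, uC of electron charge
    N_PQ = 6, N_Pc = 0.05, N_P700 = 0.05, N_A = 0.03,
    # chain rate constants, uC/s at unit driving fractions
    V_PSII = 5,       # PSII water->PQ photochemistry at reference flux
    V_b6f = 500,      # PQ pool -> plastocyanin via cytochrome b6f
    k_PcP700 = 30,    # plastocyanin <-> P700 exchange
    V_PSI = 100,      # P700 -> acceptor-side photochemistry
    pq_sat_exp = 4,   # cooperativity of PSII acceptor-side saturation
    V_DH_basal = 0.06,  # endogenous dehydrogenase reduction of PQ
    k_DH_NADPH = 0.04,  # extra DH flux per mM NADPH
    k_DH_succ = 0.03,   # extra DH flux per mM succinate
    V_TO = 0.015,     # terminal oxidases, PQH2 -> O2
    k_A_recomb = 0.006, # PSI acceptor-side charge recombination
    # light coupling weights per wavelength (nm)
    w_PSII = c("680" = 1, "700" = 0.2, "730" = 0.02),
    w_PSI = c("680" = 1, "700" = 1, "730" = 0.6),
    reference_flux = 50,  # umol photons m^-2 s^-1 == unit light drive
    # interfacial pathways
    cofactors = cofactor_table(),
    # inhibitor block fractions in [0, 1]
    block_DCMU = 0, block_HQNO = 0,
    # substrate concentrations, mM
    NADPH = 0, succinate = 0,
    # flags
    mediator_present = FALSE, oxygen_removed = FALSE, strain = "WT",
    # electrode
    E_app = 300, scale = 1,
    # initial reduced fractions (PQ pool, Pc, P700, PSI acceptor);
    # a light-adapted (oxidised) start, so the protocol's leading dark
    # segment sets the dark-adaptation state
    init = c(r_PQ = 0, r_Pc = 0, r_P700 = 0, r_A = 0),
    # noise model (applied after integration), uA and uA/s
    noise_sigma = 0.05, drift = 0,
    # output grid
    dt_out = 0.05,
    seed = 1L,
    # cyclic voltammetry surface/diffusion couples
    cv = list(q_surface = 8,      # uC of surface-confined quinone
              i_mediator = 2,     # uA mediator diffusion peak current
              capacitance = 0.04, # uA per mV/s capacitive background
              cap_slope = 5e-4,   # uA per mV resistive tilt
              kinetic_shift = 0.2 # mV peak shift per mV/s scan rate
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown etc_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$N_PQ > 0, cfg$N_Pc > 0, cfg$N_P700 > 0, cfg$N_A > 0,
            cfg$block_DCMU >= 0, cfg$block_DCMU <= 1,
            cfg$block_HQNO >= 0, cfg$block_HQNO <= 1)
  if (!cfg$strain %in% c("WT", "dCydCoxArto")) {
    stop("strain must be 'WT' or 'dCydCoxArto'", call. = FALSE)
  }
  structure(cfg, class = "etc_config")
}

has_oxidases <- function(config) config$strain == "WT"

oxygen_present <- function(config) !isTRUE(config$oxygen_removed)

light_weight <- function(weights, wavelength) {
  key <- as.character(wavelength)
  if (key %in% names(weights)) return(unname(weights[key]))
  # interpolate in wavelength for non-tabulated values
  wl <- as.numeric(names(weights))
  stats::approx(wl, weights, xout = wavelength, rule = 2)$y
}

#' Illumination protocol builders
#'
#' `chopped_light_protocol()` builds the standard chopped-light schedule:
#' `n_cycles` repetitions of `off` seconds of darkness followed by `on`
#' seconds of light, with a trailing dark segment, at the given flux and
#' wavelength. `light_segment()` builds a single arbitrary segment for
#' custom schedules (e.g. pretreatment protocols); concatenate segments
#' with `rbind()`.
#'
#' @param n_cycles number of dark/light cycles.
#' @param on,off light and dark durations in seconds.
#' @param flux photon flux in umol photons m^-2 s^-1.
#' @param wavelength illumination wavelength in nm.
#' @param trailing_dark length of the final dark segment (s).
#' @return A data frame with columns `duration`, `flux`, `wavelength`.
#' @export
chopped_light_protocol <- function(n_cycles = 3, on = 60, off = 60,
                                   flux = 50, wavelength = 680,
                                   trailing_dark = off) {
  segs <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
    rbind(light_segment(off, 0, wavelength),
          light_segment(on, flux, wavelength))
  }))
  rbind(segs, light_segment(trailing_dark, 0, wavelength))
}

#' @rdname chopped_light_protocol
#' @param duration segment duration in seconds.
#' @export
light_segment <- function(duration, flux, wavelength = 680) {
  data.frame(duration = duration, flux = flux, wavelength = wavelength)
}
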