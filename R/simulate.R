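#' Simulate a chronoamperometry photocurrent experiment
#'
#' Integrates the kinetic model of the photosynthetic and respiratory
#' electron-transport chains wired to an electrode through potential-gated
#' interfacial pathways, over an illumination protocol. The state variables
#' are the reduced fractions of the plastoquinone pool, plastocyanin, P700
#' and the PSI acceptor-side pool; the measured current is the sum of the
#' interfacial pathway currents. The dark-to-light spike emerges from the
#' discharge, via PSI, of charge accumulated in the PQ pool by the
#' respiratory chain during the preceding dark period; the steady-state
#' photocurrent from continuous PSII (and cytochrome b6f) turnover wired to
#' the electrode.
#'
#' Integration uses a stiff adaptive solver ([deSolve::lsoda()]) piecewise
#' over the protocol segments, with cumulative per-pathway and per-source
#' charges carried as auxiliary states. White measurement noise and linear
#' drift are added to the current after integration under the config seed,
#' leaving the noiseless channels untouched.
#'
#' @param config an [etc_config()].
#' @param protocol illumination schedule data frame (`duration`, `flux`,
#'   `wavelength`), e.g. from [chopped_light_protocol()].
#' @param E_schedule optional vector of applied potentials (mV vs SHE), one
#'   per protocol segment; defaults to `config$E_app` throughout.
#' @param state optional initial state (reduced fractions) to continue from.
#' @return A list of class `sim_result`:
#'   \describe{
#'     \item{trace}{a [ts_trace()] with `current` (noisy when the noise
#'       model is on), `potential` and `stimulus` channels;}
#'     \item{clean_current}{the noiseless current (uA);}
#'     \item{p700}{a [p700_trace()] of the oxidised-P700 fraction from the
#'       same integration;}
#'     \item{ledger}{per-pathway interfacial charge (uC) by trapezoidal
#'       quadrature on the output grid — the same quadrature as the current
#'       integral, so the ledger sums to the integral of the noiseless
#'       current exactly;}
#'     \item{conservation}{solver-accurate cumulative electron budget:
#'       sources (PSII, dehydrogenases), sinks (electrode, oxidases,
#'       recombination) and pool charge change;}
#'     \item{states}{state trajectories on the output grid;}
#'     \item{windows}{generator-recorded light windows;}
#'     \item{final_state}{reduced fractions at the end, for chaining.}
#'   }
#' @export
simulate_photocurrent <- function(config = etc_config(),
                                  protocol = chopped_light_protocol(),
                                  E_schedule = NULL, state = NULL) {
  stopifnot(inherits(config, "etc_config"))
  if (is.null(E_schedule)) E_schedule <- rep(config$E_app, nrow(protocol))
  stopifnot(length(E_schedule) == nrow(protocol))
  path <- pathway_params(config)
  y <- c(config$init,
         stats::setNames(rep(0, length(path$names) + 4L),
                  c(paste0("Q_", path$names),
                    "Qsrc_PSII", "Qsrc_DH", "Qsnk_TO", "Qsnk_rec")))
  if (!is.null(state)) y[names(state)] <- state
  y0 <- y
  dt <- config$dt_out
  t0 <- 0
  out_list <- vector("list", nrow(protocol))
  for (k in seq_len(nrow(protocol))) {
    seg <- protocol[k, ]
    forc <- list(
      E = E_schedule[k],
      L = seg$flux / config$reference_flux,
      wII = light_weight(config$w_PSII, seg$wavelength),
      wI = light_weight(config$w_PSI, seg$wavelength))
    times <- seq(0, seg$duration, by = dt)
    deriv <- make_etc_deriv(config, path, forc)
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failure in segment ", k,
           " (E_app = ", forc$E, " mV); config seed ", config$seed,
           call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    block <- as.data.frame(sol)
    block$time <- block$time + t0
    block$E_app <- forc$E
    block$flux <- seg$flux
    # recompute pathway currents on the grid for the trace and ledger
    cur <- t(apply(sol[, -1, drop = FALSE], 1, function(yy) {
      pathway_currents(yy, config, path, forc)
    }))
    colnames(cur) <- path$names
    block <- cbind(block, as.data.frame(cur))
    block$current <- rowSums(cur) * config$scale
    # the shared boundary sample belongs to the segment that starts there,
    # so light-on and potential-step edges land on their nominal times
    if (k < nrow(protocol)) block <- block[-nrow(block), , drop = FALSE]
    out_list[[k]] <- block
    t0 <- t0 + seg$duration
  }
  res <- do.call(rbind, out_list)
  clean <- res$current
  noisy <- clean
  if (config$noise_sigma > 0 || config$drift != 0) {
    withr_seed <- config$seed
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    noisy <- clean + stats::rnorm(length(clean), sd = config$noise_sigma) +
      config$drift * res$time
    old()
  }
  md <- experiment_metadata(
    E_app = if (length(unique(res$E_app)) == 1L) res$E_app[1] else NULL,
    wavelength = protocol$wavelength[1],
    photon_flux = max(protocol$flux),
    oxygen_removed = config$oxygen_removed,
    mediator_present = config$mediator_present,
    substrates = c(NADPH = config$NADPH, succinate = config$succinate),
    strain = config$strain)
  trace <- ts_trace(res$time, noisy, potential = res$E_app,
                    stimulus = res$flux, metadata = md)
  ledger <- vapply(path$names, function(nm) {
    trapz(res$time, res[[nm]]) * config$scale
  }, numeric(1))
  windows <- protocol_windows(protocol)
  p700 <- p700_trace(res$time, 1 - res$r_P700, windows = windows)
  conservation <- list(
    injected = unname(y["Qsrc_PSII"] + y["Qsrc_DH"]),
    electrode = unname(sum(y[paste0("Q_", path$names)])),
    oxidase = unname(y["Qsnk_TO"]),
    recombination = unname(y["Qsnk_rec"]),
    pool_change = pool_charge(y, config) - pool_charge(y0, config))
  structure(list(trace = trace, clean_current = clean, p700 = p700,
                 ledger = ledger, conservation = conservation,
                 states = res[c("time", names(config$init))],
                 windows = windows,
                 final_state = y[names(config$init)],
                 config = config, protocol = protocol,
                 E_schedule = E_schedule),
            class = "sim_result")
}

# restore RNG state on exit so simulation seeding does not perturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() rm(".Random.seed", envir = globalenv())
  }
}

pool_charge <- function(y, config) {
  unname(y["r_PQ"] * config$N_PQ + y["r_Pc"] * config$N_Pc +
         y["r_P700"] * config$N_P700 + y["r_A"] * config$N_A)
}

protocol_windows <- function(protocol) {
  t_end <- cumsum(protocol$duration)
  t_start <- c(0, t_end[-length(t_end)])
  lit <- which(protocol$flux > 0)
  if (!length(lit)) return(empty_photoperiods())
  rows <- lapply(lit, function(k) {
    dark_start <- if (k > 1L) {
      prev_lit <- lit[lit < k]
      if (length(prev_lit)) t_end[max(prev_lit)] else 0
    } else 0
    data.frame(t_on = t_start[k], t_off = t_end[k],
               preceding_dark_start = dark_start,
               dark_adaptation_time = t_start[k] - dark_start)
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("photoperiods", "data.frame"))
}

pathway_params <- function(config) {
  tab <- config$cofactors
  active <- vapply(seq_len(nrow(tab)), function(i) {
    req <- tab$requires[i]
    (req != "mediator" || config$mediator_present) &&
      (req != "oxidase" || has_oxidases(config))
  }, logical(1))
  list(tab = tab, active = active, names = tab$name)
}

chain_fluxes <- function(y, config, path, forc) {
  r_PQ <- min(max(y[["r_PQ"]], 0), 1)
  r_Pc <- min(max(y[["r_Pc"]], 0), 1)
  r_P7 <- min(max(y[["r_P700"]], 0), 1)
  r_A <- min(max(y[["r_A"]], 0), 1)
  tab <- path$tab
  g <- function(nm) {
    i <- match(nm, tab$name)
    gate_fraction(forc$E, tab$E_gate[i], tab$gate_width[i])
  }
  k_et <- function(nm) tab$k_et[match(nm, tab$name)] *
    (path$active[match(nm, tab$name)])
  v_PSII <- config$V_PSII * forc$wII * forc$L * (1 - config$block_DCMU) *
    (1 - r_PQ^config$pq_sat_exp)
  j_psii <- k_et("psii_qb") * g("psii_qb") * v_PSII
  j_shuttle <- k_et("mediator_couple") * g("mediator_couple") * v_PSII
  v_DH <- (config$V_DH_basal + config$k_DH_NADPH * config$NADPH +
             config$k_DH_succ * config$succinate) * (1 - r_PQ)
  # HQNO binds the Q_n site: it blocks the haem c_n -> electrode route but
  # leaves the high-potential chain (PQH2 -> Rieske -> cyt f -> Pc) intact
  v_b6f <- config$V_b6f * r_PQ * (1 - r_Pc)
  j_b6f <- k_et("cytb6f_cn") * g("cytb6f_cn") * v_b6f *
    (1 - config$block_HQNO)
  v_TO <- config$V_TO * r_PQ * oxygen_present(config) *
    has_oxidases(config)
  j_relay <- k_et("oxidase_relay") * max(0, r_PQ - (1 - g("oxidase_relay")))
  j_pqdir <- k_et("pq_pool") * max(0, r_PQ - (1 - g("pq_pool")))
  v_PcP7 <- config$k_PcP700 * (r_Pc * (1 - r_P7) - (1 - r_Pc) * r_P7)
  v_PSIph <- config$V_PSI * forc$wI * forc$L * r_P7 * (1 - r_A)
  j_Adir <- k_et("psi_acceptor") * max(0, r_A - (1 - g("psi_acceptor")))
  j_Amed <- k_et("psi_acceptor_med") *
    max(0, r_A - (1 - g("psi_acceptor_med")))
  v_rec <- config$k_A_recomb * r_A
  list(v_PSII = v_PSII, v_DH = v_DH, v_b6f = v_b6f, v_TO = v_TO,
       v_PcP7 = v_PcP7, v_PSIph = v_PSIph, v_rec = v_rec,
       j = c(psii_qb = j_psii, cytb6f_cn = j_b6f, psi_acceptor = j_Adir,
             psi_acceptor_med = j_Amed, oxidase_relay = j_relay,
             pq_pool = j_pqdir, mediator_couple = j_shuttle))
}

make_etc_deriv <- function(config, path, forc) {
  function(t, y, parms) {
    f <- chain_fluxes(y, config, path, forc)
    j <- f$j
    to_pool <- f$v_PSII - j[["psii_qb"]] - j[["mediator_couple"]]
    to_Pc <- f$v_b6f - j[["cytb6f_cn"]]
    d <- c(
      r_PQ = (to_pool + f$v_DH - f$v_b6f - f$v_TO - j[["oxidase_relay"]] -
                j[["pq_pool"]]) / config$N_PQ,
      r_Pc = (to_Pc - f$v_PcP7) / config$N_Pc,
      r_P700 = (f$v_PcP7 - f$v_PSIph) / config$N_P700,
      r_A = (f$v_PSIph - j[["psi_acceptor"]] - j[["psi_acceptor_med"]] -
               f$v_rec) / config$N_A)
    list(c(d, j[path$names], f$v_PSII, f$v_DH, f$v_TO, f$v_rec))
  }
}

pathway_currents <- function(y, config, path, forc) {
  chain_fluxes(y, config, path, forc)$j[path$names]
}

#' Simulate a stepped chronoamperometry scan
#'
#' Runs one dark/light photoperiod per applied-potential step, carrying the
#' membrane redox state across steps, and concatenates the result into a
#' single trace with a staircase potential channel.
#'
#' @param config an [etc_config()].
#' @param potentials vector of applied potentials (mV vs SHE), applied in
#'   the order given.
#' @param dark,on dark-adaptation and illumination durations per step (s).
#' @param flux,wavelength illumination per step.
#' @return A `sim_result` (see [simulate_photocurrent()]).
#' @export
simulate_stepped_ca <- function(config = etc_config(),
                                potentials = seq(-700, 700, by = 100),
                                dark = 60, on = 60, flux = 50,
                                wavelength = 680) {
  protocol <- do.call(rbind, lapply(potentials, function(E) {
    rbind(light_segment(dark, 0, wavelength),
          light_segment(on, flux, wavelength))
  }))
  # trailing dark so the last photoperiod has a following dark reference
  protocol <- rbind(protocol, light_segment(dark, 0, wavelength))
  E_schedule <- c(rep(potentials, each = 2L),
                  potentials[length(potentials)])
  simulate_photocurrent(config, protocol, E_schedule = E_schedule)
}

#' Simulate a P700 absorbance-difference recording
#'
#' Runs [simulate_photocurrent()] and returns the P700 channel: the
#' oxidised-P700 fraction from the same integration, so photocurrent and
#' optical signal share one clock and one set of state variables.
#'
#' @inheritParams simulate_photocurrent
#' @return A [p700_trace()].
#' @export
simulate_p700 <- function(config = etc_config(),
                          protocol = chopped_light_protocol()) {
  simulate_photocurrent(config, protocol)$p700
}

#' Simulate a cyclic voltammogram
#'
#' Closed-form voltammogram of the membrane-bound quinone couple (ideal
#' Nernstian surface wave, peak current proportional to scan rate) and,
#' when a mediator is present, a diffusing one-electron couple (peaks split
#' symmetrically about its midpoint by 57/n mV), superposed on a linear
#' capacitive background. A small kinetic peak shift proportional to scan
#' rate makes the surface-couple peak separation collapse to zero in the
#' slow-scan limit.
#'
#' @param config an [etc_config()]; couple midpoints and electron counts
#'   come from `config$cofactors`, amplitudes from `config$cv`.
#' @param vertices length-2 scan limits, mV vs SHE.
#' @param rate scan rate, mV/s (> 0).
#' @param cycles number of triangular cycles.
#' @param couples which couples to include: any of `"quinone"`,
#'   `"mediator"`. The mediator wave additionally requires
#'   `config$mediator_present`.
#' @param dE potential resolution of the synthesized scan, mV.
#' @param noise_sigma optional white noise (uA) added under the config
#'   seed.
#' @return A [voltammogram()].
#' @export
simulate_cv <- function(config = etc_config(), vertices = c(-200, 600),
                        rate = 10, cycles = 1,
                        couples = c("quinone", "mediator"), dE = 1,
                        noise_sigma = 0) {
  if (rate <= 0) stop("scan rate must be > 0", call. = FALSE)
  vertices <- sort(vertices)
  up <- seq(vertices[1], vertices[2], by = dE)
  down <- seq(vertices[2], vertices[1], by = -dE)
  E <- rep(c(up[-length(up)], down[-length(down)]), cycles)
  E <- c(E, vertices[1])
  dir <- sign(c(diff(E), -dE))
  kT <- 25.693  # mV, RT/F at 25 C
  tab <- config$cofactors
  i <- numeric(length(E))
  shift <- config$cv$kinetic_shift * rate
  if ("quinone" %in% couples) {
    row <- tab[tab$name == "pq_pool", ]
    n <- row$n_electrons
    # ideal surface wave: i = n^2 (F/RT) nu Gamma x(1-x), peak at E_m
    x <- stats::plogis(n * (E - (row$E_m + dir * shift)) / kT)
    i <- i + dir * config$cv$q_surface * n / kT * rate * x * (1 - x) * 4 *
      0.25  # x(1-x) peaks at 1/4; factor keeps peak = q n nu / (4 kT) * 4
  }
  if ("mediator" %in% couples && config$mediator_present) {
    row <- tab[tab$name == "mediator_couple", ]
    n <- row$n_electrons
    Ep <- row$E_m + dir * (28.5 / n + shift)
    u <- n * (E - Ep) / kT
    i <- i + dir * config$cv$i_mediator / cosh(u / 2)^2 *
      (1 + 0.2 * tanh(-dir * u / 4))  # mild diffusive asymmetry
  }
  i <- i + dir * config$cv$capacitance * rate +
    config$cv$cap_slope * (E - mean(vertices))
  if (noise_sigma > 0) {
    restore <- .Random.seed_exists()
    set.seed(config$seed)
    i <- i + stats::rnorm(length(i), sd = noise_sigma)
    restore()
  }
  voltammogram(E, i, scan_rate = rate)
}
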