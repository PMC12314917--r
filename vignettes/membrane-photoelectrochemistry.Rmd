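---
title: "Photoelectrochemistry of thylakoid-membrane electrodes: methods and model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoelectrochemistry of thylakoid-membrane electrodes: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thylakem)
```

# The measurement

A cyanobacterial thylakoid membrane adsorbed on a porous transparent
electrode exchanges electrons with it through several parallel routes, each
becoming thermodynamically available only above a characteristic applied
potential. Chronoamperometry under chopped light (60 s on / 60 s off at
50 µmol photons m⁻² s⁻¹, 680 nm, +300 mV vs SHE as the standard condition)
produces a stereotyped profile: a sharp anodic spike at the dark→light
transition, relaxation to an elevated light steady state, and a rapid
return to the dark level at light-off. Two parameters summarise it:

* **Spike Charge** (µC): the charge in the transient spike, interpreted as
  the discharge, through photosystem I (PSI), of reducing charge that the
  respiratory chain accumulated in the plastoquinone (PQ) pool during the
  preceding dark period. It grows with dark-adaptation time, with
  PQ-reducing substrates (NADPH, succinate), and in strains lacking the
  PQ-oxidising terminal oxidases.
* **Steady State Photocurrent** (µA): the sustained light-minus-dark
  current difference, carried by continuous photosystem II (PSII) and
  cytochrome *b₆f* turnover wired to the electrode; abolished by the PSII
  inhibitor DCMU.

# Feature extraction: definitions and rationale

The analysis software behind published traces of this kind is typically
bespoke and unpublished, so this package fixes explicit, parameter-light
definitions:

* **Dark level and noise** — mean of the final 25% of the preceding dark
  segment; noise σ is the standard deviation of the same segment after
  removing a linear fit, so slow drift does not inflate it. A dark segment
  of at least 4 s is required.
* **Steady State Photocurrent** — mean over the final 25% of the light
  window, minus a dark reference linearly interpolated between the
  preceding and following dark levels. The reference is evaluated at the
  centroid of the light-window tail (not the window midpoint): only then
  does a linear baseline drift cancel exactly, which is the property the
  correction exists for. Without a following dark segment the preceding
  level is used and the record flagged. Negative values are reported
  signed, with a flag.
* **Spike Charge** — the spike window runs from light-on to the first time
  the current falls to ≤ (light steady level + 3σ) and stays there for
  ≥ 1 s, capped at light-off; the charge is the trapezoidal integral of
  (current − light steady level) over that window. Integrating above the
  *light* steady level (not the dark level) makes spike and steady-state
  features partition the light-period charge without double counting.
  Negative integrals are clipped to zero and flagged.
* **Onset potential** — most negative applied potential at which a feature
  exceeds `max(k·σ, 0.1·max(feature))` and stays above it at every more
  positive step up to the feature's maximum (k = 3 by default). The
  persistence clause discards single-step noise exceedances; the relative
  floor is the method's stated detection resolution and keeps the rule
  meaningful for noise-free synthetic scans, where σ → 0 would otherwise
  make any positive value "detected".
* **Decay onset** — the low-potential plateau is the set of steps within
  10% of the most negative step's value (at least two steps required); the
  decay onset is the most negative step below 90% of the plateau mean with
  all more positive steps also below.
* **Group statistics** — replicate summaries use mean ± SEM and two-tailed
  unpaired *t*-tests in Welch's unequal-variance form (the equal-variance
  choice is never safe by default and the two coincide for balanced, equal
  variance designs).

# The kinetic simulator

No published rate equations exist for this preparation, so the generator
defines its own minimal network, built to reproduce the *potential-resolved
observables* rather than absolute magnitudes. State variables are the
reduced fractions of four pools — PQ (capacity 6 µC), plastocyanin
(0.05 µC), P700 (0.05 µC) and the PSI acceptor side (0.03 µC) — with
fluxes (µC/s ≡ µA):

* PSII photochemistry `V_PSII·w_II(λ)·L·(1 − r_PQ⁴)` (water → PQ); the
  quartic saturation expresses that the Q_B site finds oxidised quinone
  easily until the pool is nearly full, and lets the PSII input throttle
  only under genuine pool backup.
* Cytochrome *b₆f* `V_b6f·r_PQ·(1 − r_Pc)` (PQ → plastocyanin), fast, so
  the chain, not the pool exchange, limits throughput.
* Plastocyanin ⇌ P700 exchange and PSI photochemistry
  `V_PSI·w_I(λ)·L·r_P700·(1 − r_A)`.
* Respiratory dehydrogenases `(V_DH + k_N·[NADPH] + k_S·[succinate])·(1 −
  r_PQ)` reducing PQ in light and dark; terminal oxidases `V_TO·r_PQ`
  (wild type with oxygen only); a slow acceptor-side recombination sink.

Electrode coupling uses two forms. *Flux diversions* send a gated share of
an instantaneous chain flux to the electrode — a fraction
`k·gate(E)` of the PSII flux at the Q_B site (gate −100 mV) and of the
*b₆f* flux at haem c_n (gate +100 mV; this is the route HQNO blocks).
Diversions carry photocurrent but cannot drain the dark store, because the
fluxes they tap vanish in darkness. *Pool contacts* oxidise a standing
pool down to its Nernst equilibrium, `j = k_et·max(0, r − r_eq(E))` with
`r_eq(E) = logistic((E_gate − E)/w)`, `w = 30 mV`: the PSI acceptor side
(−100 mV direct; −600 mV via a soluble mediator when present), the
oxidase relay (+150 mV) and direct PQH₂ oxidation (+250 mV). The
equilibrium limit, not the rate gate, is what makes charge-integral
features switch on sharply: an amplitude gate alone lets a slow trickle
move the whole store across the window and smears every onset.

Wavelength weights (`w_II` = 1/0.2/0.02 and `w_I` = 1/1/0.6 at
680/700/730 nm) are declared model defaults chosen so far-red light
excites PSI selectively. Light flux is normalised to the 50 µmol photons
m⁻² s⁻¹ reference.

## How the observables emerge

* **Steady-state onset (−100 mV) and maximum (+100 mV).** Below −100 mV
  every electrode route is closed; the pool backs up and PSII throttles, so
  the steady current is a few percent of maximal. At −100 mV the
  Q_B diversion and the acceptor-side contact half-open. Between 0 and
  +100 mV the chain's exit is still capacity-limited by the acceptor-side
  contact, and the haem c_n gate opening at +100 mV relieves that
  bottleneck — the steady state reaches its plateau there and not before.
* **Spike plateau and decay (+200/+300 mV).** The spike charge equals the
  dark-accumulated store wherever the discharge completes within the light
  window, so it is flat from −100 to +100 mV. The oxidase relay
  (wild type) starts draining the store *in the dark* once the pool is
  more reduced than its gate equilibrium, which first bites at +200 mV;
  without oxidases the first dark drain is direct PQH₂ oxidation at
  +300 mV. The gate centres sit 50 mV below those observed onsets
  because a Nernst-limited drain only removes the store above its
  equilibrium level; the calibration is applied to the observable.
* **Mediated PSI onset (−600 mV).** With the mediator present the acceptor
  side discharges through a high-capacity contact gated at −600 mV; one
  step more negative the equilibrium pins the acceptor pool reduced and
  the store can only trickle, which the feature definitions classify as
  steady current, not spike.
* **P700.** The optical signal is the oxidised-P700 fraction from the same
  integration, so spike and oxidation maximum are causally simultaneous;
  the dark re-reduction is supply-limited by the dehydrogenase flux, hence
  faster with NADPH.

## Numerical choices

Stiff integration uses `deSolve::lsoda` (rtol 1e-8, atol 1e-10) piecewise
over protocol segments, with per-pathway and per-source cumulative charges
carried as auxiliary states; electron conservation holds to ~1e-13
relative. The output grid is 0.05 s — fine enough to resolve the
sub-second discharge front at open gates, which a coarser grid
under-integrates. The boundary sample of each protocol segment belongs to
the segment that starts there, so detected light-on edges coincide with
the generator's schedule. The charge ledger is computed by trapezoidal
quadrature on the output grid, the same quadrature as the current
integral, so the two agree exactly by construction. Measurement noise
(white, default σ = 1% of the steady-state amplitude; optional linear
drift) is added after integration under the config seed; identical
config + seed is bit-reproducible, and changing only the seed changes only
the noise. Simulations start from a fully oxidised (light-adapted) state,
so the leading dark segment of a protocol defines the dark adaptation and
every staircase step sees the same accumulation dynamics.

Cyclic voltammograms are closed-form, not ODE output: an ideal Nernstian
surface wave for the membrane quinone couple (n = 2, E_m +77 mV; peak
current ∝ scan rate; a small kinetic shift of 0.2 mV per mV/s makes the
peak separation collapse in the slow-scan limit) and a diffusion-shaped
one-electron wave for the mediator couple (E_m +420 mV, peaks split
±28.5 mV), on a linear capacitive background that the analysis removes
with a per-sweep quadratic fitted outside the faradaic exclusion window.

# What the generator does and does not emulate

It emulates the *structure* the analysis assumes: chopped-light profiles
with dark-adaptation-dependent spikes, inhibitor and wavelength
selectivity, staircase scans with pathway onsets at the experimentally
observed potentials, co-registered P700 transients, white noise and slow
drift. Passing tests on simulator output therefore demonstrates that the
pipeline recovers known structure from realistic-shaped data; it does not
validate the model against real membranes. Known limitations:

* Absolute magnitudes (µA, µC) are set by an arbitrary flux-to-current
  scale; only ratios and potentials are meaningful.
* Wet-lab effect sizes are not calibration targets: the model yields
  mild NADPH fold changes (≈1.4× spike) and a mild HQNO steady-state
  reduction, where experiments report much larger values. In particular,
  flux blocked at haem c_n partially reroutes through the PSI leg, so
  HQNO's full experimental phenotype (strong steady-state inhibition with
  an untouched spike) is outside this architecture.
* The mediator acts as an electron shuttle above its midpoint and as a
  PSI-acceptor contact; its role as a P700 *donor* at very negative
  potentials (closing a complete cycle through the cell) is not modelled —
  the −600 mV spike is powered by the dark-accumulated store.
* Ferredoxin/FNR flux is zero (lost during membrane isolation); cyclic
  electron flow, spatial membrane geometry and Marcus/Butler–Volmer
  interfacial kinetics are out of scope.

# Problem sizes

The test-suite and acceptance runs use 15-step (−700…+700 mV) and 9-step
(−100…+700 mV) staircases with one 60 s/60 s photoperiod per step,
two-to-three-cycle chopped protocols, 1 mV voltammogram resolution, and
20 randomised configurations for the closed-loop charge checks — sizes at
which every derived potential is grid-exact and a full run completes in a
few minutes on one core.
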