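#' Time-series trace of a potentiostat (or spectrophotometer) recording
#'
#' `ts_trace()` builds the canonical container used throughout the package:
#' a data frame with a strictly increasing `time` column (seconds), a
#' `current` column (microamperes, anodic positive) and optional `potential`
#' (mV vs SHE) and `stimulus` (photon flux, umol photons m^-2 s^-1) channels,
#' together with experiment metadata.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param current numeric vector of currents in microamperes (anodic
#'   positive), same length as `time`, finite everywhere.
#' @param potential optional numeric vector of applied potentials in mV vs
#'   SHE.
#' @param stimulus optional numeric vector of light flux in
#'   umol photons m^-2 s^-1.
#' @param metadata an [experiment_metadata()] object (or `NULL`).
#'
#' @return An object of class `ts_trace`: a data frame with columns `time`,
#'   `current` and any optional channels, plus a `metadata` attribute.
#' @seealso [read_trace()], [write_trace()], [resample_uniform()]
#' @export
ts_trace <- function(time, current, potential = NULL, stimulus = NULL,
                     metadata = NULL) {
  time <- as.numeric(time)
  current <- as.numeric(current)
  if (length(time) != length(current)) {
    stop("`time` and `current` must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) {
    stop("a trace must contain at least one sample", call. = FALSE)
  }
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop(sprintf("time must be strictly increasing; first violation at row %d",
                 bad[1] + 1L), call. = FALSE)
  }
  if (!all(is.finite(current))) {
    stop("current must be finite everywhere", call. = FALSE)
  }
  df <- data.frame(time = time, current = current)
  for (ch in c("potential", "stimulus")) {
    v <- get(ch)
    if (!is.null(v)) {
      v <- as.numeric(v)
      if (length(v) != length(time)) {
        stop(sprintf("channel `%s` must match the time vector length", ch),
             call. = FALSE)
      }
      df[[ch]] <- v
    }
  }
  structure(df,
            metadata = metadata %||% experiment_metadata(),
            class = c("ts_trace", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment metadata attached to a trace
#'
#' Captures the conditions a recording was made under. Units follow the
#' package's canonical scales: chlorophyll a loading in micrograms, applied
#' potential in mV vs SHE, photon flux in umol photons m^-2 s^-1,
#' temperature in degrees Celsius.
#'
#' @param chl_loading chlorophyll a loading in micrograms (must be > 0 when
#'   given).
#' @param E_app applied potential in mV vs SHE for fixed-potential runs.
#' @param wavelength illumination wavelength in nm.
#' @param photon_flux photon flux in umol photons m^-2 s^-1.
#' @param pH electrolyte pH.
#' @param temperature cell temperature in degrees C (must lie in (0, 60)).
#' @param reference_electrode_offset additive offset (mV) that was applied to
#'   convert raw potentials to the SHE scale.
#' @param oxygen_removed logical; enzymatic oxygen removal active.
#' @param mediator_present logical; exogenous redox mediator in the
#'   electrolyte.
#' @param inhibitors named numeric vector of inhibitor concentrations.
#' @param substrates named numeric vector of substrate concentrations.
#' @param strain strain label, e.g. `"WT"` or `"dCydCoxArto"`.
#'
#' @return A list with class `experiment_metadata`.
#' @export
experiment_metadata <- function(chl_loading = NULL, E_app = NULL,
                                wavelength = NULL, photon_flux = NULL,
                                pH = NULL, temperature = NULL,
                                reference_electrode_offset = 0,
                                oxygen_removed = FALSE,
                                mediator_present = FALSE,
                                inhibitors = numeric(),
                                substrates = numeric(),
                                strain = "WT") {
  if (!is.null(chl_loading) && chl_loading <= 0) {
    stop("chl_loading must be > 0 when provided", call. = FALSE)
  }
  if (!is.null(temperature) &&
      (temperature <= 0 || temperature >= 60)) {
    stop("temperature must lie in (0, 60) degrees C", call. = FALSE)
  }
  structure(list(
    chl_loading = chl_loading, E_app = E_app, wavelength = wavelength,
    photon_flux = photon_flux, pH = pH, temperature = temperature,
    reference_electrode_offset = reference_electrode_offset,
    oxygen_removed = isTRUE(oxygen_removed),
    mediator_present = isTRUE(mediator_present),
    inhibitors = inhibitors, substrates = substrates,
    strain = strain
  ), class = "experiment_metadata")
}

#' @export
print.ts_trace <- function(x, ...) {
  span <- range(x$time)
  cat(sprintf("<ts_trace> %d samples, %.1f-%.1f s, channels: %s\n",
              nrow(x), span[1], span[2],
              paste(setdiff(names(x), "time"), collapse = ", ")))
  invisible(x)
}

trace_metadata <- function(trace) attr(trace, "metadata", exact = TRUE)

trace_dt <- function(trace) {
  d <- diff(trace$time)
  stats::median(d)
}

is_uniform <- function(trace, tol = 1e-6) {
  d <- diff(trace$time)
  length(d) == 0L || (max(d) - min(d)) <= tol * max(d)
}
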