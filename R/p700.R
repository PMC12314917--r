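#' P700 absorbance-difference trace
#'
#' Container for a Joliot-type spectrophotometer recording of the oxidised
#' P700 fraction (arbitrary absorbance-difference units, linear in the
#' oxidised fraction). Illumination windows use the same representation as
#' photocurrent photoperiods so the two can be co-analysed on a shared
#' clock.
#'
#' @param time sample times in seconds, strictly increasing.
#' @param signal absorbance-difference signal (arbitrary units,
#'   proportional to oxidised P700).
#' @param windows optional [detect_photoperiods()]-style data frame of
#'   illumination windows.
#' @param clock_offset declared offset (s) between this trace's clock and a
#'   co-registered photocurrent trace (0 = shared clock).
#' @return An object of class `p700_trace`.
#' @export
p700_trace <- function(time, signal, windows = NULL, clock_offset = 0) {
  stopifnot(length(time) == length(signal))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  structure(data.frame(time = time, signal = signal),
            windows = windows, clock_offset = clock_offset,
            class = c("p700_trace", "data.frame"))
}

#' Steady-state P700 oxidation of a light window
#'
#' Mean signal over the final 25% of the light window minus the
#' pre-illumination dark mean (final 25% of the preceding dark segment),
#' i.e. the light-induced oxidation on top of the dark baseline.
#'
#' @param trace a [p700_trace()].
#' @param window one illumination window (`t_on`, `t_off`,
#'   `preceding_dark_start`).
#' @return Steady-state oxidation in signal units.
#' @export
p700_steady_state <- function(trace, window) {
  if (window$t_off - window$t_on < 8) {
    stop("light window shorter than 8 s", call. = FALSE)
  }
  dark_sel <- trace$time >= window$t_on -
    0.25 * (window$t_on - window$preceding_dark_start) &
    trace$time < window$t_on
  light_sel <- trace$time >= window$t_off -
    0.25 * (window$t_off - window$t_on) & trace$time < window$t_off
  dark <- if (any(dark_sel)) mean(trace$signal[dark_sel]) else 0
  mean(trace$signal[light_sel]) - dark
}

#' Dark re-reduction rate of P700
#'
#' Fits a single-exponential decay `s(t) = a * exp(-k t) + c` to the signal
#' over a dark-decay window starting at light-off and returns the rate
#' constant `k` (1/s) with fit diagnostics.
#'
#' @param trace a [p700_trace()].
#' @param t_off time of light-off (s); the fit starts here.
#' @param t_end end of the decay window (s); defaults to the trace end.
#' @return A list of class `p700_kinetics_fit`: `rate` (1/s), `amplitude`,
#'   `offset`, `residual_rms`.
#' @export
rereduction_rate <- function(trace, t_off, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(trace$time)
  sel <- trace$time >= t_off & trace$time <= t_end
  tt <- trace$time[sel] - t_off
  ss <- trace$signal[sel]
  if (length(tt) < 5L) stop("decay window too short to fit", call. = FALSE)
  a0 <- ss[1] - min(ss)
  span <- max(ss) - min(ss)
  if (a0 <= 0 || span <= 10 * .Machine$double.eps * max(abs(ss), 1)) {
    stop("fit failure: signal does not decay over the window", call. = FALSE)
  }
  # crude initial rate from the time to fall to a0/e
  below <- which(ss - min(ss) <= a0 / exp(1))
  k0 <- if (length(below)) 1 / max(tt[below[1]], 1e-3) else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(ss ~ a * exp(-k * tt) + c,
                      start = list(a = a0, k = k0, c = min(ss)),
                      lower = c(a = 0, k = 1e-6, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rms <- sqrt(mean(res^2))
  if (cf[["a"]] < 2 * rms || cf[["k"]] < 1e-4) {
    stop("fit failure: signal does not decay over the window", call. = FALSE)
  }
  structure(list(rate = unname(cf[["k"]]), amplitude = unname(cf[["a"]]),
                 offset = unname(cf[["c"]]), residual_rms = rms),
            class = "p700_kinetics_fit")
}

#' Co-analyse a photocurrent trace and a P700 trace
#'
#' For co-registered recordings (shared clock, declared offset), reports the
#' time lag between the spike-peak current and the P700 oxidation maximum of
#' each light window, flagging simultaneity when |lag| < 1 s. Because the
#' oxidation saturates to a plateau, its "maximum" is taken as the first
#' time the signal reaches 95% of the window maximum (measured above the
#' pre-illumination dark baseline), which is robust to flat plateaus.
#'
#' @param photo a [ts_trace()] photocurrent recording.
#' @param p700 a [p700_trace()] on the same clock.
#' @param windows illumination windows; detected from `photo`'s stimulus
#'   channel when omitted.
#' @return A data frame with one row per window: `t_spike_peak`,
#'   `t_p700_max`, `lag` (s), `simultaneous` (|lag| < 1 s), `flag`.
#' @export
coanalyze <- function(photo, p700, windows = NULL) {
  if (is.null(windows)) windows <- detect_photoperiods(photo, "stimulus")
  offset <- attr(p700, "clock_offset") %||% 0
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    sel <- photo$time >= w$t_on & photo$time < w$t_off
    tt <- photo$time[sel]; ii <- photo$current[sel]
    db <- tryCatch(dark_baseline(photo, w)$level, error = function(e) min(ii))
    if (max(ii) - db <= 0) {
      return(data.frame(t_spike_peak = NA_real_, t_p700_max = NA_real_,
                        lag = NA_real_, simultaneous = NA,
                        flag = "no_spike"))
    }
    t_peak <- tt[which.max(ii)]
    ps <- p700$time - offset
    sel7 <- ps >= w$t_on & ps < w$t_off
    s <- p700$signal[sel7]; ts7 <- ps[sel7]
    dark_sel <- ps >= w$t_on - 0.25 * w$dark_adaptation_time & ps < w$t_on
    base <- if (any(dark_sel)) mean(p700$signal[dark_sel]) else min(s)
    rise <- s - base
    if (max(rise) <= 0) {
      return(data.frame(t_spike_peak = t_peak, t_p700_max = NA_real_,
                        lag = NA_real_, simultaneous = NA,
                        flag = "no_p700_response"))
    }
    t_max <- ts7[which(rise >= 0.95 * max(rise))[1]]
    lag <- t_max - t_peak
    data.frame(t_spike_peak = t_peak, t_p700_max = t_max, lag = lag,
               simultaneous = abs(lag) < 1, flag = NA_character_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Synthetic single-exponential P700 dark decay
#'
#' Closed-form generator of a P700 re-reduction transient: a plateau during
#' light followed at light-off by `a * exp(-k (t - t_off)) + c`, with
#' optional white noise. Used as the independent reference when checking
#' the kinetics fit.
#'
#' @param k decay rate constant (1/s).
#' @param a amplitude (signal units); `c` dark offset.
#' @param t_off light-off time (s); `t_end` trace end; `dt` sampling
#'   interval.
#' @param noise_sd white-noise standard deviation (signal units).
#' @param c dark offset.
#' @return A [p700_trace()] spanning `[0, t_end]`.
#' @export
synth_p700_decay <- function(k, a = 1, c = 0, t_off = 10, t_end = 40,
                             dt = 0.01, noise_sd = 0) {
  tt <- seq(0, t_end, by = dt)
  s <- ifelse(tt < t_off, a + c, a * exp(-k * (tt - t_off)) + c)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), sd = noise_sd)
  p700_trace(tt, s)
}
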