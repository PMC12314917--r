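#' Dark baseline level and noise of a photoperiod
#'
#' The dark current is estimated as the mean over the final 25% of the dark
#' segment preceding illumination; the noise level is the standard deviation
#' of the same segment after removing a linear trend, so slow drift does not
#' inflate it.
#'
#' @param trace a uniformly sampled [ts_trace()].
#' @param window one row of a [detect_photoperiods()] result (or a list with
#'   `t_on` and `preceding_dark_start`).
#' @return A list with `level` (uA) and `noise_sigma` (uA).
#' @export
dark_baseline <- function(trace, window) {
  t0 <- window$preceding_dark_start
  t1 <- window$t_on
  if (t1 - t0 < 4) {
    stop(sprintf("dark segment before t_on = %.1f s is shorter than 4 s",
                 t1), call. = FALSE)
  }
  tail_start <- t1 - 0.25 * (t1 - t0)
  sel <- trace$time >= tail_start & trace$time < t1
  seg_t <- trace$time[sel]
  seg_i <- trace$current[sel]
  level <- mean(seg_i)
  res <- stats::lm.fit(cbind(1, seg_t), seg_i)$residuals
  list(level = level, noise_sigma = stats::sd(res))
}

light_tail <- function(trace, window) {
  t_on <- window$t_on; t_off <- window$t_off
  tail_start <- t_off - 0.25 * (t_off - t_on)
  sel <- trace$time >= tail_start & trace$time < t_off
  list(level = mean(trace$current[sel]),
       t_mid = (tail_start + t_off) / 2)
}

#' Steady State Photocurrent of a photoperiod
#'
#' The positive difference between the light and dark steady-state currents.
#' The light level is the mean over the final 25% of the light window; the
#' dark reference is obtained by linearly interpolating the preceding and
#' following dark levels to the light-window midpoint, which cancels linear
#' baseline drift. When no following dark segment exists the preceding level
#' is used and the result is flagged. Negative values are returned as
#' computed, with a flag.
#'
#' @inheritParams dark_baseline
#' @param following optional next window (for the following dark level);
#'   found automatically by [extract_features()].
#' @return A list with `steady_state` (uA), `flag` (character or NA).
#' @export
steady_state_photocurrent <- function(trace, window, following = NULL) {
  if (window$t_off - window$t_on < 8) {
    stop("light segment shorter than 8 s", call. = FALSE)
  }
  pre <- dark_baseline(trace, window)
  pre_t <- window$t_on - 0.125 * (window$t_on - window$preceding_dark_start)
  lt <- light_tail(trace, window)
  flag <- NA_character_
  t_end_dark <- if (!is.null(following)) following$t_on else
    max(trace$time)
  if (t_end_dark - window$t_off >= 4) {
    post_sel <- trace$time >= t_end_dark - 0.25 * (t_end_dark - window$t_off) &
      trace$time < t_end_dark
    post_level <- mean(trace$current[post_sel])
    post_t <- t_end_dark - 0.125 * (t_end_dark - window$t_off)
    # interpolate the dark reference to the centroid of the light tail, so
    # a linear baseline drift cancels exactly
    w <- (lt$t_mid - pre_t) / (post_t - pre_t)
    dark_ref <- (1 - w) * pre$level + w * post_level
  } else {
    dark_ref <- pre$level
    flag <- "no_following_dark"
  }
  ss <- lt$level - dark_ref
  if (ss < 0 && is.na(flag)) flag <- "negative_steady_state"
  list(steady_state = ss, flag = flag)
}

#' Spike Charge of a photoperiod
#'
#' Integrates the transient current spike at the dark-to-light transition.
#' The spike window runs from light-on to the first time the current falls
#' to at or below (light steady level + `k_sigma` * noise) and stays there
#' for at least `persist` seconds, capped at light-off. The charge is the
#' trapezoidal integral of (current - light steady level) over that window,
#' so the spike and the Steady State Photocurrent partition the light-period
#' charge without double counting. Negative integrals are clipped to zero
#' and flagged.
#'
#' @inheritParams dark_baseline
#' @param light_level light steady-state current (uA); computed from the
#'   final 25% of the light window when omitted.
#' @param noise_sigma dark-baseline noise (uA); computed via
#'   [dark_baseline()] when omitted.
#' @param k_sigma spike-end threshold multiplier (default 3).
#' @param persist time (s) the current must remain below threshold.
#' @return A list with `charge` (uC), `spike_window_end` (s), `flag`.
#' @export
spike_charge <- function(trace, window, light_level = NULL,
                         noise_sigma = NULL, k_sigma = 3, persist = 1) {
  if (is.null(light_level)) light_level <- light_tail(trace, window)$level
  if (is.null(noise_sigma)) noise_sigma <- dark_baseline(trace, window)$noise_sigma
  sel <- which(trace$time >= window$t_on & trace$time < window$t_off)
  tt <- trace$time[sel]
  ii <- trace$current[sel]
  thr <- light_level + k_sigma * noise_sigma
  dt <- stats::median(diff(tt))
  n_persist <- max(1L, round(persist / dt))
  below <- ii <= thr
  t_end <- window$t_off
  if (any(below)) {
    # first index from which `below` holds for n_persist consecutive samples
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & runs$lengths >= n_persist)
    # also accept a trailing shorter run that reaches the window end
    if (!length(hit)) {
      last <- length(runs$values)
      if (runs$values[last]) hit <- last
    }
    if (length(hit)) t_end <- tt[starts[hit[1]]]
  }
  int_sel <- tt <= t_end
  flag <- NA_character_
  if (sum(int_sel) >= 2L) {
    q <- trapz(tt[int_sel], ii[int_sel] - light_level)
  } else q <- 0
  if (q < 0) { q <- 0; flag <- "negative_spike_clipped" }
  list(charge = q, spike_window_end = t_end, flag = flag)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Extract photocurrent features for every photoperiod
#'
#' Runs [dark_baseline()], [steady_state_photocurrent()] and
#' [spike_charge()] on each window and assembles one record per photoperiod.
#' Per-window failures are isolated into flagged rows with `NA` features;
#' the batch never aborts. When the trace metadata carries a chlorophyll
#' loading, chl-normalised columns (per ug chl a) are appended.
#'
#' @param trace a uniformly sampled [ts_trace()].
#' @param windows a [detect_photoperiods()] result.
#' @param chl_normalise add `spike_charge_per_chl` / `steady_state_per_chl`
#'   columns when a chl loading is available (default FALSE; raw uC and uA
#'   are primary).
#' @return A data frame of class `photocurrent_features`, one row per window:
#'   `spike_charge` (uC), `steady_state_photocurrent` (uA), `dark_current`
#'   (uA), `noise_sigma` (uA), `spike_window_end` (s), `E_app` (mV vs SHE,
#'   from the potential channel or metadata), `dark_adaptation_time` (s),
#'   `flag`.
#' @export
extract_features <- function(trace, windows, chl_normalise = FALSE) {
  stopifnot(inherits(trace, "ts_trace"))
  md <- trace_metadata(trace)
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    following <- if (k < nrow(windows)) windows[k + 1L, ] else NULL
    res <- tryCatch({
      db <- dark_baseline(trace, w)
      ss <- steady_state_photocurrent(trace, w, following)
      lt <- light_tail(trace, w)
      sp <- spike_charge(trace, w, light_level = lt$level,
                         noise_sigma = db$noise_sigma)
      E <- if (!is.null(trace$potential)) {
        stats::median(trace$potential[trace$time >= w$t_on &
                                      trace$time < w$t_off])
      } else md$E_app %||% NA_real_
      flag <- stats::na.omit(c(ss$flag, sp$flag))
      data.frame(spike_charge = sp$charge,
                 steady_state_photocurrent = ss$steady_state,
                 dark_current = db$level, noise_sigma = db$noise_sigma,
                 spike_window_end = sp$spike_window_end,
                 E_app = E, dark_adaptation_time = w$dark_adaptation_time,
                 flag = if (length(flag)) paste(flag, collapse = ";")
                        else NA_character_)
    }, error = function(e) {
      data.frame(spike_charge = NA_real_,
                 steady_state_photocurrent = NA_real_,
                 dark_current = NA_real_, noise_sigma = NA_real_,
                 spike_window_end = NA_real_, E_app = NA_real_,
                 dark_adaptation_time = w$dark_adaptation_time,
                 flag = paste0("error: ", conditionMessage(e)))
    })
    res
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  if (chl_normalise && !is.null(md$chl_loading)) {
    out$spike_charge_per_chl <- out$spike_charge / md$chl_loading
    out$steady_state_per_chl <- out$steady_state_photocurrent / md$chl_loading
  }
  structure(out, class = c("photocurrent_features", "data.frame"))
}

#' Relative change of a parameter versus a control
#'
#' `100 * (treated - control) / control`, so inhibition is negative.
#'
#' @param treated,control group means (scalars).
#' @return Percentage change; `NA` with a warning when the control mean is 0.
#' @export
relative_change <- function(treated, control) {
  if (!is.finite(control) || control == 0) {
    warning("relative change undefined for zero control mean")
    return(NA_real_)
  }
  100 * (treated - control) / control
}

#' Summarise replicate measurements of a photocurrent parameter
#'
#' Mean, standard error of the mean, and a two-tailed unpaired Welch t-test
#' against a control group. With a single replicate the SEM and p-value are
#' flagged unavailable; with zero within-group variance the t statistic is
#' degenerate and flagged.
#'
#' @param values numeric vector of replicate values.
#' @param control optional numeric vector of control replicate values.
#' @return A list of class `group_summary`: `mean`, `sem`, `n`,
#'   `relative_change_pct` (vs the control mean), `p_value`, `flag`.
#' @export
aggregate_replicates <- function(values, control = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("at least one replicate value required", call. = FALSE)
  flag <- NA_character_
  sem <- if (n >= 2L) stats::sd(values) / sqrt(n) else {
    flag <- "sem_unavailable_n1"; NA_real_
  }
  rel <- NA_real_; p <- NA_real_
  if (!is.null(control)) {
    control <- control[is.finite(control)]
    rel <- relative_change(mean(values), mean(control))
    if (n >= 2L && length(control) >= 2L) {
      if (stats::sd(values) == 0 && stats::sd(control) == 0) {
        p <- if (mean(values) == mean(control)) 1 else NA_real_
        flag <- paste(stats::na.omit(c(flag, "degenerate_variance")),
                      collapse = ";")
      } else {
        p <- stats::t.test(values, control, var.equal = FALSE)$p.value
      }
    } else {
      flag <- paste(stats::na.omit(c(flag, "p_unavailable")), collapse = ";")
    }
  }
  structure(list(mean = mean(values), sem = sem, n = n,
                 relative_change_pct = rel, p_value = p, flag = flag),
            class = "group_summary")
}
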