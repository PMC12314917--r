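#' Photocurrent features as a function of applied potential
#'
#' Builds the feature-vs-E_app table of a stepped chronoamperometry
#' experiment: per potential step, the photocurrent features averaged over
#' the photoperiods the step contains. Rows are sorted by ascending E_app
#' regardless of acquisition order; steps without a photoperiod yield a
#' flagged row with missing features.
#'
#' @param trace a uniformly sampled [ts_trace()] with a potential channel.
#' @param steps a [detect_potential_steps()] result.
#' @param condition optional condition label carried into the result.
#' @return A data frame of class `potential_scan` with columns `E_app`,
#'   `spike_charge`, `steady_state_photocurrent`, `noise_sigma`,
#'   `n_photoperiods`, `flag`.
#' @export
features_vs_potential <- function(trace, steps = NULL, condition = NULL) {
  if (is.null(steps)) steps <- detect_potential_steps(trace)
  per_step <- attr(steps, "photoperiods")
  rows <- lapply(seq_len(nrow(steps)), function(k) {
    wins <- per_step[[k]]
    if (is.null(wins) || nrow(wins) == 0L) {
      return(data.frame(E_app = steps$E_app[k], spike_charge = NA_real_,
                        steady_state_photocurrent = NA_real_,
                        noise_sigma = NA_real_, n_photoperiods = 0L,
                        flag = "no_photoperiod"))
    }
    ft <- extract_features(trace, wins)
    data.frame(E_app = steps$E_app[k],
               spike_charge = mean(ft$spike_charge, na.rm = TRUE),
               steady_state_photocurrent =
                 mean(ft$steady_state_photocurrent, na.rm = TRUE),
               noise_sigma = mean(ft$noise_sigma, na.rm = TRUE),
               n_photoperiods = nrow(wins),
               flag = NA_character_)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$E_app), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, condition = condition,
            class = c("potential_scan", "data.frame"))
}

scan_feature <- function(scan, feature = c("spike_charge", "steady_state")) {
  feature <- match.arg(feature)
  col <- if (feature == "steady_state") "steady_state_photocurrent" else
    "spike_charge"
  v <- scan[[col]]
  if (all(!is.finite(v))) {
    stop(sprintf("feature column '%s' is entirely missing", col),
         call. = FALSE)
  }
  v
}

#' Onset potential of a photocurrent feature
#'
#' The most negative applied potential at which the feature is detected and
#' stays detected at every more positive step up to the feature's maximum.
#' Detection means exceeding `max(k * sigma, rel_floor * max(feature))`:
#' the noise term is the spec of a statistically visible response, and the
#' relative floor is the method's stated detection resolution, which keeps
#' the rule meaningful for noise-free synthetic scans (sigma ~ 0). The
#' persistence requirement discards single-row noise exceedances.
#'
#' @param scan a [features_vs_potential()] result with >= 2 rows.
#' @param feature `"spike_charge"` or `"steady_state"`.
#' @param k noise multiplier (default 3). Larger `k` never yields a more
#'   negative onset.
#' @param rel_floor detection resolution as a fraction of the scan maximum
#'   (default 0.1).
#' @return Onset potential in mV vs SHE, or `NA` ("none") when the feature
#'   never exceeds threshold.
#' @export
onset_potential <- function(scan, feature = c("spike_charge", "steady_state"),
                            k = 3, rel_floor = 0.1) {
  if (nrow(scan) < 2L) stop("scan must have at least 2 rows", call. = FALSE)
  v <- scan_feature(scan, feature)
  sigma <- scan$noise_sigma
  sigma[!is.finite(sigma)] <- 0
  vmax <- max(v, na.rm = TRUE)
  if (!is.finite(vmax) || vmax <= 0) return(NA_real_)
  i_max <- which.max(ifelse(is.finite(v), v, -Inf))
  thr <- pmax(k * sigma, rel_floor * vmax)
  above <- is.finite(v) & v > thr
  for (i in seq_len(nrow(scan))) {
    upto <- i:i_max
    if (i <= i_max && all(above[upto])) return(scan$E_app[i])
  }
  if (above[i_max]) return(scan$E_app[i_max])
  NA_real_
}

#' Potential at which a feature first reaches its scan maximum
#'
#' The most negative applied potential whose feature lies within
#' `tolerance_pct` of the scan maximum.
#'
#' @inheritParams onset_potential
#' @param tolerance_pct tolerance in percent of the maximum (default 5).
#' @return Potential in mV vs SHE.
#' @export
feature_maximum_potential <- function(scan,
                                      feature = c("spike_charge",
                                                  "steady_state"),
                                      tolerance_pct = 5) {
  v <- scan_feature(scan, feature)
  if (sum(is.finite(v)) < 2L) stop("scan must have >= 2 finite rows",
                                   call. = FALSE)
  vmax <- max(v, na.rm = TRUE)
  if (vmax <= 0) stop("flat zero scan: no maximum identifiable",
                      call. = FALSE)
  ok <- is.finite(v) & v >= (1 - tolerance_pct / 100) * vmax
  scan$E_app[which(ok)[1]]
}

#' Decay onset of the Spike Charge at positive potentials
#'
#' Identifies the low-potential plateau of the spike-charge-vs-potential
#' curve (all rows within `plateau_tol` of the most-negative-row value;
#' at least 2 such rows are required) and returns the most negative applied
#' potential at which the feature falls below `fraction` of the plateau
#' mean with every more positive row also below.
#'
#' @param scan a [features_vs_potential()] result.
#' @param feature feature to analyse (the spike charge).
#' @param fraction decay threshold as a fraction of the plateau mean
#'   (default 0.9).
#' @param plateau_tol relative tolerance defining plateau membership
#'   (default 0.1).
#' @return Decay-onset potential in mV vs SHE, or `NA` ("none") for a
#'   monotone non-decreasing scan.
#' @export
decay_onset <- function(scan, feature = "spike_charge", fraction = 0.9,
                        plateau_tol = 0.1) {
  v <- scan_feature(scan, feature)
  fin <- which(is.finite(v))
  if (!length(fin)) stop("no finite feature values", call. = FALSE)
  ref <- v[fin[1]]
  plateau_idx <- fin[abs(v[fin] - ref) <= plateau_tol * abs(ref)]
  if (length(plateau_idx) < 2L || ref <= 0) {
    stop("no low-potential plateau identifiable", call. = FALSE)
  }
  plateau <- mean(v[plateau_idx])
  below <- v < fraction * plateau
  below[!is.finite(v)] <- FALSE
  n <- nrow(scan)
  for (i in seq_len(n)) {
    if (below[i] && all(below[i:n] | !is.finite(v[i:n]))) {
      return(scan$E_app[i])
    }
  }
  NA_real_
}
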