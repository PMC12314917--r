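#' Cyclic voltammogram container
#'
#' A data frame of (potential, current, sweep, cycle) samples from a
#' triangular potential program, with the scan rate attached.
#'
#' @param potential potentials in mV vs SHE.
#' @param current currents in uA.
#' @param scan_rate scan rate in mV/s (> 0).
#' @param sweep integer sweep index (odd = anodic-going, even =
#'   cathodic-going); derived from the potential program when omitted.
#' @param cycle integer cycle index.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current, scan_rate, sweep = NULL,
                         cycle = NULL) {
  if (scan_rate <= 0) stop("scan_rate must be > 0", call. = FALSE)
  n <- length(potential)
  stopifnot(length(current) == n)
  if (is.null(sweep)) {
    # forward differences: a vertex sample opens the new sweep
    dE <- diff(potential)
    dir <- sign(c(dE, dE[length(dE)]))
    dir[dir == 0] <- 1
    sweep <- cumsum(c(1L, as.integer(diff(dir) != 0)))
  }
  if (is.null(cycle)) cycle <- (sweep + 1L) %/% 2L
  structure(data.frame(potential = potential, current = current,
                       sweep = sweep, cycle = cycle),
            scan_rate = scan_rate,
            class = c("voltammogram", "data.frame"))
}

#' Remove the capacitive background from a voltammogram
#'
#' Fits a low-order polynomial (degree <= 2) to each sweep's current outside
#' a faradaic exclusion window and subtracts it, removing the capacitive
#' offset and sloping background while leaving peak shapes intact.
#'
#' @param vg a [voltammogram()].
#' @param exclusion numeric length-2 window (mV vs SHE) containing the
#'   faradaic peaks, excluded from the background fit. Must lie inside the
#'   scanned range and leave at least 20% of each sweep for fitting.
#' @param degree polynomial degree (0, 1 or 2; default 2).
#' @return A baseline-corrected [voltammogram()].
#' @export
baseline_correct <- function(vg, exclusion, degree = 2) {
  stopifnot(inherits(vg, "voltammogram"), length(exclusion) == 2L)
  exclusion <- sort(exclusion)
  rng <- range(vg$potential)
  if (exclusion[1] < rng[1] || exclusion[2] > rng[2]) {
    stop("exclusion window must lie inside the scanned range", call. = FALSE)
  }
  if (degree > 2) stop("degree must be <= 2", call. = FALSE)
  out <- vg
  for (s in unique(vg$sweep)) {
    sel <- vg$sweep == s
    E <- vg$potential[sel]; i <- vg$current[sel]
    fit_sel <- E < exclusion[1] | E > exclusion[2]
    if (mean(fit_sel) < 0.2) {
      stop("exclusion window covers more than 80% of a sweep", call. = FALSE)
    }
    X <- stats::poly(E, degree = degree, raw = TRUE)
    fit <- stats::lm.fit(cbind(1, X[fit_sel, , drop = FALSE]), i[fit_sel])
    bg <- cbind(1, X) %*% fit$coefficients
    out$current[sel] <- i - as.numeric(bg)
  }
  out
}

#' Locate a redox couple and estimate its midpoint potential
#'
#' Takes a baseline-corrected voltammogram with one dominant couple, finds
#' the anodic peak (current maximum on anodic-going sweeps) and cathodic
#' peak (current minimum on cathodic-going sweeps), and reports the midpoint
#' potential `E_m = (E_pa + E_pc) / 2`. Peaks must exceed 5x the residual
#' noise of the corrected background, otherwise no couple is detected.
#'
#' @param vg a baseline-corrected [voltammogram()].
#' @param cycle which cycle to analyse (default: the last full cycle).
#' @return A list of class `redox_couple`: `E_pa`, `E_pc`, `E_m`,
#'   `peak_separation` (all mV vs SHE), `i_pa`, `i_pc` (uA).
#' @export
find_redox_peaks <- function(vg, cycle = NULL) {
  stopifnot(inherits(vg, "voltammogram"))
  if (is.null(cycle)) cycle <- max(vg$cycle)
  v <- vg[vg$cycle == cycle, , drop = FALSE]
  if (nrow(v) < 4L) stop("cycle too short", call. = FALSE)
  sweeps <- unique(v$sweep)
  dirs <- vapply(sweeps, function(s) {
    E <- v$potential[v$sweep == s]
    sign(E[length(E)] - E[1])
  }, numeric(1))
  an <- v[v$sweep %in% sweeps[dirs > 0], , drop = FALSE]
  ca <- v[v$sweep %in% sweeps[dirs < 0], , drop = FALSE]
  if (nrow(an) == 0L || nrow(ca) == 0L) {
    stop("voltammogram must contain both an anodic and a cathodic sweep",
         call. = FALSE)
  }
  noise <- stats::mad(diff(v$current)) / sqrt(2)
  floor_uA <- 1e-6  # instrument resolution floor
  i_pa <- max(an$current); i_pc <- min(ca$current)
  if (i_pa < max(5 * noise, floor_uA) && -i_pc < max(5 * noise, floor_uA)) {
    stop("no couple detected: peaks do not exceed 5x residual noise",
         call. = FALSE)
  }
  E_pa <- an$potential[which.max(an$current)]
  E_pc <- ca$potential[which.min(ca$current)]
  structure(list(E_pa = E_pa, E_pc = E_pc, E_m = (E_pa + E_pc) / 2,
                 peak_separation = E_pa - E_pc, i_pa = i_pa, i_pc = i_pc),
            class = "redox_couple")
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf("<redox_couple> E_m = %+.1f mV vs SHE (E_pa %+.1f, E_pc %+.1f, dEp %.1f mV)\n",
              x$E_m, x$E_pa, x$E_pc, x$peak_separation))
  invisible(x)
}
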