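#' Partition a trace into photoperiods
#'
#' Finds the light-on/light-off structure of a chopped-light recording.
#' With `method = "stimulus"` (the primary route) edges are taken directly
#' from the light-flux channel; with `method = "derivative"` (fallback for
#' files lacking a stimulus channel) edges are placed at maxima of |dI/dt|
#' exceeding 5x its median absolute value, merged to alternating on/off.
#'
#' Each returned window records when the light turned on (`t_on`) and off
#' (`t_off`), the start of the preceding dark segment, and the dark
#' adaptation time (the length of the dark period prior to illumination).
#'
#' @param trace a uniformly sampled [ts_trace()].
#' @param method `"stimulus"` or `"derivative"`.
#' @param min_period minimum on or off duration in seconds; shorter
#'   candidate segments are discarded as glitches.
#' @return A data frame of class `photoperiods` with columns `t_on`, `t_off`,
#'   `preceding_dark_start`, `dark_adaptation_time`. Zero rows when the trace
#'   contains no light period.
#' @export
detect_photoperiods <- function(trace, method = c("stimulus", "derivative"),
                                min_period = 5) {
  stopifnot(inherits(trace, "ts_trace"))
  method <- match.arg(method)
  if (!is_uniform(trace, tol = 1e-3)) {
    stop("trace must be uniformly sampled; see resample_uniform()",
         call. = FALSE)
  }
  tt <- trace$time
  if (method == "stimulus") {
    if (is.null(trace$stimulus)) {
      stop("method = 'stimulus' requires a stimulus channel", call. = FALSE)
    }
    on <- trace$stimulus > max(trace$stimulus, 0) / 2 & trace$stimulus > 0
    if (!any(on)) return(empty_photoperiods())
    edges <- edges_from_logical(on)
  } else {
    edges <- edges_from_derivative(trace, min_period)
    if (is.null(edges)) return(empty_photoperiods())
    on <- logical(length(tt))
    state <- edges$first_state
    idx <- c(edges$idx, length(tt) + 1L)
    pos <- 1L
    for (k in seq_along(edges$idx)) {
      # state flips at each edge; fill preceding run
      on[pos:(idx[k] - 1L)] <- state
      state <- !state
      pos <- idx[k]
    }
    on[pos:length(tt)] <- state
    edges <- edges_from_logical(on)
  }
  windows_from_on(tt, on, min_period)
}

empty_photoperiods <- function() {
  structure(data.frame(t_on = numeric(), t_off = numeric(),
                       preceding_dark_start = numeric(),
                       dark_adaptation_time = numeric()),
            class = c("photoperiods", "data.frame"))
}

edges_from_logical <- function(on) {
  d <- diff(as.integer(on))
  list(on_idx = which(d == 1L) + 1L, off_idx = which(d == -1L) + 1L)
}

# Derivative fallback: |dI/dt| peaks > 5x median absolute derivative,
# alternating; the first edge is light-on if mean current after it exceeds
# the mean before it. Candidate crossings closer than min_period belong to
# one edge (a spike transient decays over seconds), and runs whose peak
# stays below twice the detection threshold are discarded as noise.
edges_from_derivative <- function(trace, min_period = 5) {
  i <- trace$current
  d <- abs(diff(i))
  thr <- 5 * stats::median(d)
  if (thr <= 0 || !any(d > thr)) return(NULL)
  cand <- which(d > thr)
  dt <- stats::median(diff(trace$time))
  gap <- max(1L, round(min_period / dt))
  runs <- split(cand, cumsum(c(1, diff(cand) > gap)))
  runs <- runs[vapply(runs, function(r) max(d[r]) >= 2 * thr, logical(1))]
  if (!length(runs)) return(NULL)
  idx <- vapply(runs, function(r) r[which.max(d[r])] + 1L, integer(1))
  first <- idx[1]
  before <- mean(i[seq_len(first - 1L)])
  after_end <- if (length(idx) > 1L) idx[2] - 1L else length(i)
  after <- mean(i[first:after_end])
  list(idx = idx, first_state = !(after > before))
}

windows_from_on <- function(tt, on, min_period) {
  dt <- stats::median(diff(tt))
  min_n <- max(1L, round(min_period / dt))
  # drop glitch runs shorter than min_period by merging into neighbours
  r <- rle(on)
  if (length(r$lengths) > 1L) {
    short <- r$lengths < min_n
    # never merge away first/last runs into nothing
    for (k in seq_along(short)) {
      if (short[k] && length(r$values) > 1L) r$values[k] <- NA
    }
    v <- r$values
    for (k in seq_along(v)) {
      if (is.na(v[k])) v[k] <- if (k > 1L) v[k - 1L] else v[min(which(!is.na(v)))]
    }
    r$values <- v
    on <- inverse.rle(r)
  }
  e <- edges_from_logical(on)
  if (on[1]) e$on_idx <- c(1L, e$on_idx)
  out <- lapply(e$on_idx, function(i_on) {
    i_off <- e$off_idx[e$off_idx > i_on]
    t_off <- if (length(i_off)) tt[i_off[1]] else tt[length(tt)] + dt
    prev_off <- e$off_idx[e$off_idx <= i_on]
    dark_start <- if (i_on == 1L) tt[1] else if (length(prev_off))
      tt[prev_off[length(prev_off)]] else tt[1]
    data.frame(t_on = tt[i_on], t_off = t_off,
               preceding_dark_start = dark_start,
               dark_adaptation_time = tt[i_on] - dark_start)
  })
  structure(do.call(rbind, c(out, list(make.row.names = FALSE))),
            class = c("photoperiods", "data.frame"))
}

#' Partition a trace into constant-potential steps
#'
#' Splits a stepped-chronoamperometry recording into contiguous segments of
#' (near-)constant applied potential. Steps shorter than `min_dwell` are
#' merged into their neighbours; each step carries the photoperiods detected
#' within it.
#'
#' @param trace a [ts_trace()] with a potential channel.
#' @param min_step minimum potential change (mV) treated as a new step.
#' @param min_dwell minimum step duration in seconds.
#' @param photoperiods optional precomputed [detect_photoperiods()] result;
#'   computed from the stimulus channel when present otherwise.
#' @return A data frame of class `potential_steps` with columns `E_app`,
#'   `t_start`, `t_end`, `n_photoperiods`, and a `photoperiods` attribute
#'   holding the per-step window list.
#' @export
detect_potential_steps <- function(trace, min_step = 5, min_dwell = 5,
                                   photoperiods = NULL) {
  stopifnot(inherits(trace, "ts_trace"))
  if (is.null(trace$potential)) {
    stop("detect_potential_steps() requires a potential channel",
         call. = FALSE)
  }
  tt <- trace$time
  E <- trace$potential
  brk <- which(abs(diff(E)) >= min_step) + 1L
  starts <- c(1L, brk)
  ends <- c(brk - 1L, length(E))
  # merge steps shorter than min_dwell into the previous (or next) step
  keep <- (tt[ends] - tt[starts]) >= min_dwell
  if (!any(keep)) keep[which.max(tt[ends] - tt[starts])] <- TRUE
  merged_s <- integer(0); merged_e <- integer(0)
  for (k in seq_along(starts)) {
    if (keep[k]) {
      merged_s <- c(merged_s, starts[k]); merged_e <- c(merged_e, ends[k])
    } else if (length(merged_e)) {
      merged_e[length(merged_e)] <- ends[k]
    }  # leading glitch: absorbed by the following step below
  }
  if (length(merged_s) && merged_s[1] > 1L) merged_s[1] <- 1L
  # re-merge adjacent survivors whose potentials agree (glitch removal can
  # split one level into two)
  k <- 1L
  while (k < length(merged_s)) {
    E1 <- stats::median(E[merged_s[k]:merged_e[k]])
    E2 <- stats::median(E[merged_s[k + 1L]:merged_e[k + 1L]])
    if (abs(E1 - E2) < min_step) {
      merged_e[k] <- merged_e[k + 1L]
      merged_s <- merged_s[-(k + 1L)]; merged_e <- merged_e[-(k + 1L)]
    } else k <- k + 1L
  }
  if (is.null(photoperiods)) {
    photoperiods <- if (!is.null(trace$stimulus)) {
      detect_photoperiods(trace, "stimulus")
    } else empty_photoperiods()
  }
  per_step <- vector("list", length(merged_s))
  rows <- lapply(seq_along(merged_s), function(k) {
    t0 <- tt[merged_s[k]]; t1 <- tt[merged_e[k]]
    inwin <- photoperiods[photoperiods$t_on >= t0 - 1e-9 &
                          photoperiods$t_on < t1, , drop = FALSE]
    per_step[[k]] <<- inwin
    data.frame(E_app = stats::median(E[merged_s[k]:merged_e[k]]),
               t_start = t0, t_end = t1, n_photoperiods = nrow(inwin))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, photoperiods = per_step,
            class = c("potential_steps", "data.frame"))
}
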