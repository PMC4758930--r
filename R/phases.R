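# Division of the cardiac cycle into systole, E-wave, diastasis and A-wave
# from valve-plane speed traces. The E-wave runs from the onset of the rise in
# MV speed (first frame above a small fraction of the wave peak, walked back
# to the preceding local minimum) to the end of its deceleration (the local
# minimum after the peak); the A-wave is detected analogously around the
# second diastolic peak and ends at end-diastole; diastasis is the gap.

#' Cardiac phase map
#'
#' Frame-index windows (1-based) for the four phases. The windows are
#' disjoint, ordered, and jointly cover \code{1:n_frames}; \code{diastasis}
#' and (for fused inflow) \code{a_wave} may be empty.
#'
#' @param systole,e_wave,diastasis,a_wave Integer frame-index vectors.
#' @param n_frames Total number of frames.
#' @return An object of class \code{"phase_map"}.
#' @export
phase_map <- function(systole, e_wave, diastasis, a_wave, n_frames) {
  all_idx <- c(systole, e_wave, diastasis, a_wave)
  if (length(all_idx) != n_frames || anyDuplicated(all_idx) ||
      !setequal(all_idx, seq_len(n_frames)) || is.unsorted(all_idx))
    stop("domain error: phase windows must partition 1:n_frames in order")
  structure(list(systole = as.integer(systole), e_wave = as.integer(e_wave),
                 diastasis = as.integer(diastasis), a_wave = as.integer(a_wave),
                 n_frames = as.integer(n_frames)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  fmt <- function(w) if (length(w)) sprintf("%d-%d", min(w), max(w)) else "(empty)"
  cat(sprintf("<phase_map> systole %s | E-wave %s | diastasis %s | A-wave %s of %d frames\n",
              fmt(x$systole), fmt(x$e_wave), fmt(x$diastasis), fmt(x$a_wave),
              x$n_frames))
  invisible(x)
}

#' Per-frame phase labels
#' @param phases A \code{"phase_map"}.
#' @param n Number of frames (defaults to the map's).
#' @return Character vector of \code{"systole"}, \code{"e_wave"},
#'   \code{"diastasis"}, \code{"a_wave"}.
#' @export
phase_labels <- function(phases, n = phases$n_frames) {
  lab <- character(n)
  for (ph in c("systole", "e_wave", "diastasis", "a_wave"))
    lab[phases[[ph]]] <- ph
  lab
}

# light 3-point running mean, endpoints kept
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

# indices of local maxima with a minimal relative prominence
local_maxima <- function(x, idx, min_prom = 0.2) {
  rng <- range(x[idx])
  if (diff(rng) <= 0) return(integer(0))
  out <- integer(0)
  for (i in idx) {
    left <- if (i - 1 >= idx[1]) x[i - 1] else -Inf
    right <- if (i + 1 <= idx[length(idx)]) x[i + 1] else -Inf
    if (x[i] >= left && x[i] > right &&
        (x[i] - rng[1]) >= min_prom * diff(rng))
      out <- c(out, i)
  }
  out
}

# a:b that is empty (not reversed) when b < a
seq_idx <- function(a, b) if (b < a) integer(0) else a:b

# walk back from i to the preceding local minimum, not before `floor_i`
walk_back_min <- function(x, i, floor_i) {
  while (i > floor_i && x[i - 1] < x[i]) i <- i - 1L
  i
}

# walk forward from peak to the following local minimum, not past `ceil_i`
walk_fwd_min <- function(x, i, ceil_i) {
  while (i < ceil_i && x[i + 1] < x[i]) i <- i + 1L
  i
}

#' Detect cardiac phases from MV and AoV speed traces
#'
#' @param traces A \code{\link{speed_traces}} object (MV and AoV speeds per
#'   frame).
#' @param meta The \code{\link{acquisition_meta}}.
#' @param onset_frac Onset threshold as a fraction of the wave's
#'   baseline-corrected peak (default 0.05).
#' @return A \code{\link{phase_map}}. With a fused (single-peak) diastolic
#'   inflow the A-wave window is empty and a warning of class
#'   \code{"lvforce_single_wave"} is signalled. Flat traces raise a detection
#'   error. Detection is invariant to uniform scaling of the traces.
#' @export
detect_phases <- function(traces, meta, onset_frac = 0.05) {
  mv <- smooth3(traces$mv_speed)
  ao <- smooth3(traces$aov_speed)
  n <- length(mv)
  if (n < 6L) stop("detection error: too few frames")
  if (diff(range(mv)) <= 0 || max(mv) <= 0)
    stop("detection error: flat MV speed trace")
  if (diff(range(ao)) <= 0)
    stop("detection error: flat AoV speed trace")

  # systolic ejection: AoV peak, then fall-off below the onset threshold
  p_ao <- which.max(ao)
  base_ao <- min(ao)
  thr_ao <- base_ao + onset_frac * (ao[p_ao] - base_ao)
  s_end <- p_ao
  while (s_end < n && ao[s_end] > thr_ao) s_end <- s_end + 1L
  if (s_end >= n - 2L)
    stop("detection error: no diastolic window after the AoV fall-off")

  dia <- s_end:n
  peaks <- local_maxima(mv, dia)
  if (!length(peaks))
    stop("detection error: no diastolic MV peak found")
  e_pk <- peaks[1]
  a_pk <- if (length(peaks) >= 2L) peaks[length(peaks)] else NA_integer_

  base_mv <- min(mv[dia])
  thr_e <- base_mv + onset_frac * (mv[e_pk] - base_mv)
  e_on <- dia[1]
  while (e_on < e_pk && mv[e_on] < thr_e) e_on <- e_on + 1L
  e_on <- walk_back_min(mv, e_on, dia[1])
  lim <- if (is.na(a_pk)) n else a_pk
  e_min <- walk_fwd_min(mv, e_pk, lim)

  if (is.na(a_pk)) {
    warning(structure(class = c("lvforce_single_wave", "warning", "condition"),
                      list(message = "single diastolic inflow wave: E and A fused; a_wave left empty",
                           call = sys.call())))
    e_frames <- e_on:n
    return(phase_map(systole = seq_len(e_on - 1L), e_wave = e_frames,
                     diastasis = integer(0), a_wave = integer(0), n_frames = n))
  }

  thr_a <- base_mv + onset_frac * (mv[a_pk] - base_mv)
  a_on <- e_min + 1L
  while (a_on < a_pk && mv[a_on] < thr_a) a_on <- a_on + 1L
  a_on <- walk_back_min(mv, a_on, e_min + 1L)
  if (a_on <= e_min) a_on <- e_min + 1L

  e_frames <- seq_idx(e_on, e_min - 1L)
  if (!length(e_frames))
    stop("detection error: degenerate E-wave window")
  phase_map(systole = seq_len(e_on - 1L),
            e_wave = e_frames,
            diastasis = seq_idx(e_min, a_on - 1L),
            a_wave = seq_idx(a_on, n),
            n_frames = n)
}
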