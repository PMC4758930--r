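# Per-subject scalar summaries of the projected force trace. "Maximum force
# along an axis" is the maximum of the absolute signed projection within the
# wave's window, making the SAx-max/LAx-max ratio direction-agnostic and
# invariant to positive rescaling of the whole trace.

wave_window <- function(phases, wave = c("E", "A")) {
  wave <- match.arg(wave)
  win <- if (wave == "E") phases$e_wave else phases$a_wave
  if (!length(win)) stop("domain error: empty ", wave, "-wave window")
  win
}

#' SAx-max/LAx-max force ratio for a filling wave
#'
#' Peak transverse force (anteroseptal-inferolateral axis, \code{F_sax1})
#' divided by peak long-axis force (\code{F_long}), both as maxima of the
#' absolute projection within the wave's window. Values near 0 mean the force
#' is aligned with the apex-base axis; larger values mean more transverse
#' force.
#'
#' @param projected A \code{\link{project_force}} trace.
#' @param phases A \code{\link{phase_map}}.
#' @param wave \code{"E"} or \code{"A"}.
#' @return The dimensionless ratio; \code{Inf} if the long-axis peak is zero.
#' @export
sax_lax_ratio <- function(projected, phases, wave = c("E", "A")) {
  win <- wave_window(phases, wave)
  sax <- max(abs(projected$F_sax1[win]))
  lax <- max(abs(projected$F_long[win]))
  if (lax == 0) return(Inf)
  sax / lax
}

#' Time-averaged SAx-plane force magnitude over a filling wave
#'
#' Mean over the wave's frames of \code{sqrt(F_sax1^2 + F_sax2^2)} (N).
#'
#' @inheritParams sax_lax_ratio
#' @return Mean short-axis-plane force magnitude in N.
#' @export
mean_sax_force <- function(projected, phases, wave = c("E", "A")) {
  win <- wave_window(phases, wave)
  mean(sqrt(projected$F_sax1[win]^2 + projected$F_sax2[win]^2))
}

#' Orientation of a planar force loop
#'
#' Sign of the shoelace (signed polygon) area of the closed trajectory. In the
#' LAx plane the trajectory is \code{(F_long, F_sax1)}.
#'
#' @param x,y Coordinates of the trajectory over a window (>= 3 frames).
#' @param tol Area magnitude (N^2) below which the orientation is
#'   \code{"indeterminate"} (default 1e-6).
#' @return \code{"CCW"}, \code{"CW"} or \code{"indeterminate"}.
#' @export
loop_orientation <- function(x, y, tol = 1e-6) {
  if (length(x) < 3L) return("indeterminate")
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- sum(x * yn - xn * y) / 2
  if (abs(area) < tol) "indeterminate" else if (area > 0) "CCW" else "CW"
}

#' Velocity-peak to force-peak lag during early filling
#'
#' Time of the \code{|F|} peak minus the time of the MV speed peak, both
#' restricted to the E-wave window (ms). Positive values mean the force peaks
#' after the inflow velocity.
#'
#' @param traces A \code{\link{speed_traces}} object.
#' @param projected A \code{\link{project_force}} trace.
#' @param phases A \code{\link{phase_map}}.
#' @return Lag in ms.
#' @export
peak_lag <- function(traces, projected, phases) {
  win <- wave_window(phases, "E")
  fmag <- sqrt(projected$F_long^2 + projected$F_sax1^2 + projected$F_sax2^2)
  t_force <- projected$time_ms[win][which.max(fmag[win])]
  t_vel <- traces$time_ms[win][which.max(traces$mv_speed[win])]
  t_force - t_vel
}

#' Assemble all per-subject metrics
#'
#' @param projected A \code{\link{project_force}} trace.
#' @param traces A \code{\link{speed_traces}} object.
#' @param phases A \code{\link{phase_map}}.
#' @param mask A \code{\link{mask_series}} (for the end-diastolic volume).
#' @param covariates Named list of externally supplied scalars; \code{si}
#'   (sphericity index) is picked up if present.
#' @return An object of class \code{"subject_metrics"}: a named list with
#'   \code{ratio_e}, \code{ratio_a}, \code{mean_sax_e}, \code{mean_sax_a},
#'   \code{lax_max_e}, \code{lax_max_a}, \code{sax_max_e}, \code{sax_max_a}
#'   (N), \code{loop_dir_e}, \code{loop_dir_a}, \code{peak_lag_e} (ms),
#'   \code{si}, \code{edv} (mL).
#' @export
subject_metrics <- function(projected, traces, phases, mask,
                            covariates = list()) {
  win_e <- wave_window(phases, "E")
  has_a <- length(phases$a_wave) > 0L
  win_a <- if (has_a) phases$a_wave else NULL
  out <- list(
    ratio_e = sax_lax_ratio(projected, phases, "E"),
    ratio_a = if (has_a) sax_lax_ratio(projected, phases, "A") else NA_real_,
    mean_sax_e = mean_sax_force(projected, phases, "E"),
    mean_sax_a = if (has_a) mean_sax_force(projected, phases, "A") else NA_real_,
    lax_max_e = max(abs(projected$F_long[win_e])),
    lax_max_a = if (has_a) max(abs(projected$F_long[win_a])) else NA_real_,
    sax_max_e = max(abs(projected$F_sax1[win_e])),
    sax_max_a = if (has_a) max(abs(projected$F_sax1[win_a])) else NA_real_,
    loop_dir_e = loop_orientation(projected$F_long[win_e],
                                  projected$F_sax1[win_e]),
    loop_dir_a = if (has_a) loop_orientation(projected$F_long[win_a],
                                             projected$F_sax1[win_a])
                 else "indeterminate",
    peak_lag_e = peak_lag(traces, projected, phases),
    si = if (!is.null(covariates$si)) covariates$si else NA_real_,
    edv = max(mask_volumes_ml(mask)))
  structure(out, class = "subject_metrics")
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat("<subject_metrics>\n")
  cat(sprintf("  SAx-max/LAx-max ratio: E %.3f, A %s\n", x$ratio_e,
              if (is.na(x$ratio_a)) "NA" else sprintf("%.3f", x$ratio_a)))
  cat(sprintf("  mean SAx force (N):    E %.4f, A %s\n", x$mean_sax_e,
              if (is.na(x$mean_sax_a)) "NA" else sprintf("%.4f", x$mean_sax_a)))
  cat(sprintf("  LAx peak force (N):    E %.3f, A %s\n", x$lax_max_e,
              if (is.na(x$lax_max_a)) "NA" else sprintf("%.3f", x$lax_max_a)))
  cat(sprintf("  loop direction (LAx):  E %s, A %s\n", x$loop_dir_e, x$loop_dir_a))
  cat(sprintf("  E-wave peak lag: %.1f ms | EDV %.1f mL | SI %s\n",
              x$peak_lag_e, x$edv,
              if (is.na(x$si)) "NA" else sprintf("%.2f", x$si)))
  invisible(x)
}
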