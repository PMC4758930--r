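# Anatomical reference frame and planar projections. The long axis runs
# base -> apex; the three-chamber (LAx) plane is spanned by the long axis and
# the MV -> AoV direction; the basal short-axis (SAx) plane is the fixed plane
# orthogonal to the long axis. The force is a single global vector, so one
# orientation per subject suffices.

normalize3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Build the anatomical axes frame from landmarks
#'
#' \code{e_long} points base to apex; \code{e_sax1} is the in-plane
#' (three-chamber) transverse axis, signed to point from the anteroseptal
#' (aortic) side toward the inferolateral wall; \code{e_sax2} completes a
#' right-handed orthonormal triad. The origin is the LV center of mass at an
#' early-diastolic frame.
#'
#' @param landmarks An \code{\link{lv_landmarks}} object.
#' @param mask A \code{\link{mask_series}} (for the center-of-mass origin).
#' @param early_frame Frame index used for the center of mass; by convention
#'   the first E-wave frame. Accepts a phase map (its first E-wave frame is
#'   used) or an integer.
#' @return An object of class \code{"axes_frame"} with unit vectors
#'   \code{e_long}, \code{e_sax1}, \code{e_sax2} and \code{origin} (mm).
#' @export
build_axes <- function(landmarks, mask = NULL, early_frame = 1L) {
  stopifnot(inherits(landmarks, "lv_landmarks"))
  if (inherits(early_frame, "phase_map")) {
    early_frame <- if (length(early_frame$e_wave)) early_frame$e_wave[1] else 1L
  }
  e_long <- normalize3(landmarks$apex - landmarks$mv_center)
  w <- landmarks$aov_center - landmarks$mv_center
  w_perp <- w - sum(w * e_long) * e_long
  if (sqrt(sum(w_perp^2)) < 1e-9)
    stop("geometry error: landmarks are collinear; cannot span the three-chamber plane")
  # the orthogonalized vector points toward the aortic (anteroseptal) side;
  # +e_sax1 points away from it, toward the inferolateral wall
  e_sax1 <- -normalize3(w_perp)
  if (!is.null(landmarks$rv_direction)) {
    # anteroseptal lies on the septal (RV) side: e_sax1 points away from RV
    if (sum(e_sax1 * landmarks$rv_direction) > 0) e_sax1 <- -e_sax1
  }
  e_sax2 <- cross3(e_long, e_sax1)
  origin <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(mask)) {
    m <- mask$occupancy[, , , early_frame]
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    origin <- c(mean((idx[, 1] - 1) * mask$voxel_size[1]),
                mean((idx[, 2] - 1) * mask$voxel_size[2]),
                mean((idx[, 3] - 1) * mask$voxel_size[3]))
  }
  structure(list(e_long = e_long, e_sax1 = e_sax1, e_sax2 = e_sax2,
                 origin = origin),
            class = "axes_frame")
}

#' Project a force trace onto the anatomical axes
#'
#' Components are dot products with the unit axes. The LAx-plane trajectory is
#' \code{(F_long, F_sax1)}; the basal SAx-plane trajectory is
#' \code{(F_sax1, F_sax2)}. The projection preserves the force norm.
#'
#' @param trace A \code{\link{force_trace}}.
#' @param axes An \code{\link{build_axes}} axes frame.
#' @return An object of class \code{"projected_force"}: data-frame-like list
#'   with \code{frame}, \code{time_ms}, \code{Fx,Fy,Fz}, \code{F_long},
#'   \code{F_sax1}, \code{F_sax2} (N).
#' @export
project_force <- function(trace, axes) {
  stopifnot(inherits(trace, "force_trace"), inherits(axes, "axes_frame"))
  R <- cbind(axes$e_long, axes$e_sax1, axes$e_sax2)
  P <- trace$F %*% R
  structure(list(frame = seq_len(nrow(trace$F)), time_ms = trace$times,
                 Fx = trace$F[, 1], Fy = trace$F[, 2], Fz = trace$F[, 3],
                 F_long = P[, 1], F_sax1 = P[, 2], F_sax2 = P[, 3]),
            class = "projected_force")
}

#' @export
as.data.frame.projected_force <- function(x, ...) {
  data.frame(frame = x$frame, time_ms = x$time_ms, Fx = x$Fx, Fy = x$Fy,
             Fz = x$Fz, F_long = x$F_long, F_sax1 = x$F_sax1,
             F_sax2 = x$F_sax2)
}

# trilinear interpolation of one 3-D volume at a physical point (mm)
trilinear <- function(V, point, voxel_size) {
  d <- dim(V)
  g <- point / voxel_size  # 0-based continuous voxel index
  if (any(g < 0) || any(g > d - 1))
    stop("geometry error: point lies outside the velocity grid")
  i0 <- pmin(floor(g), d - 2); f <- g - i0
  i0 <- as.integer(i0) + 1L  # 1-based lower corner
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    if (wgt > 0)
      acc <- acc + wgt * V[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

#' Extract speed traces at the mitral-valve and aortic-valve landmarks
#'
#' Trilinear interpolation of the three velocity components at each landmark
#' point per frame; the trace is the Euclidean speed.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param landmarks An \code{\link{lv_landmarks}}; the MV and AoV centers must
#'   lie inside the grid.
#' @return An object of class \code{"speed_traces"} with \code{mv_speed} and
#'   \code{aov_speed} (m/s, length n_frames) and \code{time_ms}.
#' @export
extract_speed_traces <- function(field, landmarks) {
  stopifnot(inherits(field, "velocity_field"), inherits(landmarks, "lv_landmarks"))
  vs <- field$meta$voxel_size
  nf <- field$meta$n_frames
  one <- function(pt) {
    vapply(seq_len(nf), function(f) {
      v <- vapply(1:3, function(c_i)
        trilinear(field$values[, , , c_i, f], pt, vs), numeric(1))
      sqrt(sum(v^2))
    }, numeric(1))
  }
  structure(list(mv_speed = one(landmarks$mv_center),
                 aov_speed = one(landmarks$aov_center),
                 time_ms = field$meta$frame_times),
            class = "speed_traces")
}
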