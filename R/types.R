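# Domain containers. Velocity data are stored as a 5-D array indexed
# [i, j, k, component, frame] (components x,y,z in grid axes, m/s); masks as
# a 4-D logical array [i, j, k, frame]. Physical coordinates are voxel centers
# at 0-based index * voxel_size (mm), right-handed axes.

#' Acquisition metadata for a 4D flow dataset
#'
#' Bundles the physical constants and timing needed by every downstream
#' computation: the velocity-encoding limit (VENC), the voxel spacing, the
#' cardiac frame structure, and the blood properties used in the momentum
#' balance.
#'
#' @param venc Velocity-encoding limit in m/s. Velocities beyond \code{venc}
#'   alias by multiples of \code{2*venc}.
#' @param voxel_size Numeric length-3, grid spacing in mm.
#' @param n_frames Number of reconstructed cardiac frames (the frame axis is
#'   cyclic: the last frame precedes the first).
#' @param rr_interval Cardiac cycle duration in ms.
#' @param frame_times Optional frame midpoint times in ms, strictly increasing,
#'   all below \code{rr_interval}. Defaults to uniform spacing
#'   \code{rr_interval / n_frames} starting at 0, as reconstructed by
#'   retrospective gating.
#' @param rho Blood density in kg/m^3 (default 1060).
#' @param mu Dynamic viscosity of blood in N s/m^2 (default 0.004).
#' @return An object of class \code{"acquisition_meta"}.
#' @export
acquisition_meta <- function(venc, voxel_size, n_frames, rr_interval,
                             frame_times = NULL, rho = 1060, mu = 0.004) {
  venc <- as.numeric(venc)
  voxel_size <- as.numeric(voxel_size)
  n_frames <- as.integer(n_frames)
  rr_interval <- as.numeric(rr_interval)
  if (is.null(frame_times)) {
    frame_times <- (seq_len(n_frames) - 1) * rr_interval / n_frames
  }
  frame_times <- as.numeric(frame_times)
  if (!is.finite(venc) || venc <= 0)
    stop("metadata error: venc must be a positive number (m/s)")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("metadata error: voxel_size must be three positive numbers (mm)")
  if (is.na(n_frames) || n_frames < 1L)
    stop("metadata error: n_frames must be a positive integer")
  if (!is.finite(rr_interval) || rr_interval <= 0)
    stop("metadata error: rr_interval must be positive (ms)")
  if (length(frame_times) != n_frames)
    stop("metadata error: frame_times must have length n_frames")
  if (any(diff(frame_times) <= 0) || any(frame_times >= rr_interval) ||
      any(frame_times < 0))
    stop("metadata error: frame_times must be strictly increasing, in [0, rr_interval)")
  if (!is.finite(rho) || rho <= 0) stop("metadata error: rho must be positive")
  if (!is.finite(mu) || mu < 0) stop("metadata error: mu must be non-negative")
  structure(list(venc = venc, voxel_size = voxel_size, n_frames = n_frames,
                 rr_interval = rr_interval, frame_times = frame_times,
                 rho = rho, mu = mu),
            class = "acquisition_meta")
}

#' Time-resolved three-directional velocity field
#'
#' @param values 5-D numeric array \code{[i, j, k, component, frame]} of
#'   velocities in m/s; 3 components in grid axis order x, y, z.
#' @param meta An \code{\link{acquisition_meta}} object; \code{n_frames} must
#'   match the last array extent.
#' @return An object of class \code{"velocity_field"}.
#' @export
velocity_field <- function(values, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  d <- dim(values)
  if (length(d) != 5L || d[4] != 3L)
    stop("format error: velocity values must be [i, j, k, 3, frame]")
  if (d[5] != meta$n_frames)
    stop("format error: frame count does not match meta$n_frames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("format error: velocity values must be finite")
  structure(list(values = values, meta = meta), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<velocity_field> %d x %d x %d grid, %d frames, voxel %s mm, venc %.2f m/s\n",
              d[1], d[2], d[3], d[5],
              paste(format(x$meta$voxel_size), collapse = " x "), x$meta$venc))
  invisible(x)
}

#' Per-frame binary LV occupancy on the velocity grid
#'
#' @param occupancy 4-D logical array \code{[i, j, k, frame]}.
#' @param voxel_size Grid spacing in mm (length 3).
#' @param frame_times Frame midpoint times in ms (length = frame extent).
#' @return An object of class \code{"mask_series"}.
#' @export
mask_series <- function(occupancy, voxel_size, frame_times) {
  occupancy <- array(as.logical(occupancy), dim = dim(occupancy))
  d <- dim(occupancy)
  if (length(d) != 4L) stop("format error: mask occupancy must be [i, j, k, frame]")
  counts <- apply(occupancy, 4, sum)
  if (any(counts == 0L))
    stop("domain error: mask has an empty frame (no occupied voxel)")
  structure(list(occupancy = occupancy, voxel_size = as.numeric(voxel_size),
                 frame_times = as.numeric(frame_times)),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$occupancy)
  vols <- mask_volumes_ml(x)
  cat(sprintf("<mask_series> %d x %d x %d grid, %d frames, volume %.1f-%.1f mL\n",
              d[1], d[2], d[3], d[4], min(vols), max(vols)))
  invisible(x)
}

#' Per-frame mask volume in mL
#'
#' @param mask A \code{\link{mask_series}}.
#' @return Numeric vector, one volume (mL) per frame.
#' @export
mask_volumes_ml <- function(mask) {
  vox_ml <- prod(mask$voxel_size) / 1e3  # mm^3 -> mL
  apply(mask$occupancy, 4, sum) * vox_ml
}

#' Anatomical landmarks of the LV base and apex
#'
#' @param apex,mv_center,aov_center Points in mm (grid physical coordinates):
#'   the LV apex, the mitral-valve orifice center and the aortic-valve / LV
#'   outflow-tract center.
#' @param rv_direction Optional unit vector pointing toward the right ventricle
#'   (septal side); used only to fix the sign of the short-axis axis.
#' @return An object of class \code{"lv_landmarks"}.
#' @export
lv_landmarks <- function(apex, mv_center, aov_center, rv_direction = NULL) {
  apex <- as.numeric(apex); mv_center <- as.numeric(mv_center)
  aov_center <- as.numeric(aov_center)
  if (length(apex) != 3L || length(mv_center) != 3L || length(aov_center) != 3L)
    stop("geometry error: landmark points must have 3 coordinates (mm)")
  if (sqrt(sum((apex - mv_center)^2)) < 1e-9)
    stop("geometry error: apex coincides with the mitral-valve center")
  lax <- apex - mv_center
  w <- aov_center - mv_center
  cr <- c(lax[2] * w[3] - lax[3] * w[2],
          lax[3] * w[1] - lax[1] * w[3],
          lax[1] * w[2] - lax[2] * w[1])
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(lax^2)) * max(sqrt(sum(w^2)), 1e-12))
    stop("geometry error: apex, MV and AoV landmarks are collinear")
  if (!is.null(rv_direction)) {
    rv_direction <- as.numeric(rv_direction)
    rv_direction <- rv_direction / sqrt(sum(rv_direction^2))
  }
  structure(list(apex = apex, mv_center = mv_center, aov_center = aov_center,
                 rv_direction = rv_direction),
            class = "lv_landmarks")
}

# internal: physical coordinates (mm) of voxel centers along one axis
axis_coords <- function(n, h) (seq_len(n) - 1) * h
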