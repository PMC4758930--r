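# File I/O: NIfTI volumes for velocities and masks, JSON sidecars for
# acquisition metadata and landmarks, CSV for traces and metrics. The JSON
# sidecar is the authority on physical units and grid spacing; NIfTI headers
# are written for interoperability but not trusted on read.

# parse a speed quantity that may be a bare number (m/s) or a string with a
# unit, e.g. "100 cm/s"
parse_speed <- function(x, what = "venc") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*(m/s|cm/s|mm/s)$", x))[[1]]
  if (length(m) != 3L)
    stop(sprintf("metadata error: cannot parse %s value '%s'", what, x))
  val <- as.numeric(m[2])
  val * switch(m[3], "m/s" = 1, "cm/s" = 0.01, "mm/s" = 0.001)
}

#' Read acquisition metadata from a JSON sidecar
#'
#' Recognized keys: \code{venc} (number in m/s or string such as
#' \code{"100 cm/s"}), \code{voxel_size_mm}, \code{n_frames},
#' \code{rr_interval_ms}, optional \code{frame_times_ms}, \code{rho_kg_m3},
#' \code{mu_Ns_m2}, and the storage declaration \code{velocity_unit}
#' (\code{"m/s"}, \code{"cm/s"} or \code{"mm/s"}) with optional
#' \code{velocity_scale} multiplier.
#'
#' @param path Path to the sidecar JSON file.
#' @return A list with \code{meta} (an \code{\link{acquisition_meta}}) and
#'   \code{scale}, the factor converting stored values to m/s.
#' @export
read_sidecar <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(s$venc)) stop("metadata error: sidecar is missing 'venc'")
  if (is.null(s$voxel_size_mm)) stop("metadata error: sidecar is missing 'voxel_size_mm'")
  if (is.null(s$n_frames)) stop("metadata error: sidecar is missing 'n_frames'")
  if (is.null(s$rr_interval_ms)) stop("metadata error: sidecar is missing 'rr_interval_ms'")
  meta <- acquisition_meta(
    venc = parse_speed(s$venc, "venc"),
    voxel_size = s$voxel_size_mm,
    n_frames = s$n_frames,
    rr_interval = s$rr_interval_ms,
    frame_times = s$frame_times_ms,
    rho = if (is.null(s$rho_kg_m3)) 1060 else s$rho_kg_m3,
    mu = if (is.null(s$mu_Ns_m2)) 0.004 else s$mu_Ns_m2)
  unit <- if (is.null(s$velocity_unit)) "m/s" else s$velocity_unit
  scale <- parse_speed(paste("1", unit), "velocity_unit") *
    (if (is.null(s$velocity_scale)) 1 else as.numeric(s$velocity_scale))
  list(meta = meta, scale = scale)
}

#' Read a velocity field from per-component NIfTI volumes
#'
#' Each component file holds a 4-D volume (i, j, k, frame). Values are
#' converted to m/s using the sidecar's storage declaration.
#'
#' @param paths Character length-3: NIfTI paths for the x, y, z velocity
#'   components (grid axis order).
#' @param sidecar Path to the JSON sidecar (see \code{\link{read_sidecar}}).
#' @return A \code{\link{velocity_field}}.
#' @export
read_velocity <- function(paths, sidecar) {
  if (length(paths) != 3L)
    stop("format error: expected three component files (x, y, z)")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("format error: component file missing: ", paste(missing, collapse = ", "))
  sc <- read_sidecar(sidecar)
  comps <- lapply(paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) == 3L) a <- array(a, c(dim(a), 1L))
    a
  })
  dims <- vapply(comps, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("format error: component volumes have mismatched shapes: ",
         paste(dims, collapse = " vs "))
  d <- dim(comps[[1]])
  if (d[4] != sc$meta$n_frames)
    stop("format error: file frame count (", d[4], ") does not match sidecar n_frames (",
         sc$meta$n_frames, ")")
  values <- array(0, c(d[1:3], 3L, d[4]))
  for (c_i in 1:3) values[, , , c_i, ] <- comps[[c_i]] * sc$scale
  velocity_field(values, sc$meta)
}

#' Write a velocity field as per-component NIfTI volumes plus a JSON sidecar
#'
#' @param field A \code{\link{velocity_field}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default \code{"vel"}).
#' @return Invisibly, the paths written (components then sidecar).
#' @export
write_velocity <- function(field, dir, prefix = "vel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- field$meta
  paths <- file.path(dir, paste0(prefix, "_", c("x", "y", "z"), ".nii"))
  for (c_i in 1:3) {
    vol <- field$values[, , , c_i, , drop = TRUE]
    if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(m$voxel_size, m$rr_interval / m$n_frames)
    RNifti::writeNifti(img, paths[c_i])
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(
    venc = m$venc, voxel_size_mm = m$voxel_size, n_frames = m$n_frames,
    rr_interval_ms = m$rr_interval, frame_times_ms = m$frame_times,
    rho_kg_m3 = m$rho, mu_Ns_m2 = m$mu, velocity_unit = "m/s",
    velocity_scale = 1), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}

#' Read a segmentation / mask series from a NIfTI label volume
#'
#' @param path 4-D NIfTI (i, j, k, frame); nonzero voxels are occupied.
#' @param voxel_size Grid spacing in mm; if \code{NULL}, taken from the NIfTI
#'   header pixdim.
#' @param frame_times Frame midpoint times in ms; if \code{NULL}, uniform over
#'   \code{rr_interval}.
#' @param rr_interval Cycle duration in ms (needed when \code{frame_times} is
#'   \code{NULL}).
#' @return A \code{\link{mask_series}} on the segmentation's own grid.
#' @export
read_mask <- function(path, voxel_size = NULL, frame_times = NULL,
                      rr_interval = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) a <- array(a, c(dim(a), 1L))
  if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(img)[1:3]
  nf <- dim(a)[4]
  if (is.null(frame_times)) {
    if (is.null(rr_interval))
      stop("metadata error: need frame_times or rr_interval for the mask time base")
    frame_times <- (seq_len(nf) - 1) * rr_interval / nf
  }
  mask_series(a != 0, voxel_size, frame_times)
}

#' Write a mask series as a NIfTI label volume
#' @param mask A \code{\link{mask_series}}.
#' @param path Output NIfTI path.
#' @return Invisibly, \code{path}.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$occupancy), dim(mask$occupancy)))
  RNifti::pixdim(img) <- c(mask$voxel_size,
                           if (length(mask$frame_times) > 1)
                             diff(mask$frame_times[1:2]) else 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read LV landmarks from JSON
#'
#' Expected keys: \code{apex_mm}, \code{mv_center_mm}, \code{aov_center_mm},
#' optional \code{rv_direction}.
#' @param path JSON file path.
#' @return An \code{\link{lv_landmarks}} object.
#' @export
read_landmarks <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv_landmarks(s$apex_mm, s$mv_center_mm, s$aov_center_mm, s$rv_direction)
}

#' @rdname read_landmarks
#' @param landmarks An \code{\link{lv_landmarks}} object to write.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(apex_mm = landmarks$apex,
                            mv_center_mm = landmarks$mv_center,
                            aov_center_mm = landmarks$aov_center,
                            rv_direction = landmarks$rv_direction),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a projected force trace as CSV
#'
#' One row per cardiac frame with columns \code{frame}, \code{time_ms},
#' \code{Fx}, \code{Fy}, \code{Fz}, \code{F_long}, \code{F_sax1},
#' \code{F_sax2}, \code{phase}.
#'
#' @param projected A projected force trace (see \code{\link{project_force}}).
#' @param phases A \code{\link{detect_phases}} phase map used to label frames.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_force_trace <- function(projected, phases, path) {
  df <- as.data.frame(projected)
  df$phase <- phase_labels(phases, nrow(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-subject metrics (or a cohort table) as CSV
#'
#' @param metrics A \code{subject_metrics} row (named list), a list of them, or
#'   a data.frame (cohort table).
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_metrics <- function(metrics, path) {
  if (is.data.frame(metrics)) {
    df <- metrics
  } else if (!is.null(names(metrics)) && !is.list(metrics[[1]])) {
    df <- as.data.frame(metrics[!vapply(metrics, is.null, TRUE)])
  } else {
    df <- do.call(rbind, lapply(metrics, function(m)
      as.data.frame(m[!vapply(m, is.null, TRUE)])))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
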