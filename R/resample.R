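#' Resample a segmentation series onto a velocity field's grid and time base
#'
#' Spatial resampling is voxel-center nearest neighbor (the grids are assumed
#' co-registered, sharing origin and orientation); temporal resampling picks,
#' for each velocity frame, the segmentation frame nearest in normalized cycle
#' time (cyclic distance, earlier frame on ties). Supports e.g. a 30-frame
#' morphological segmentation against a 40-frame velocity reconstruction.
#'
#' @param seg A \code{\link{mask_series}} on the segmentation's own grid/time
#'   base.
#' @param target A \code{\link{velocity_field}} defining the output grid and
#'   frame times.
#' @return A \code{\link{mask_series}} on the target grid, one frame per
#'   velocity frame.
#' @export
resample_mask <- function(seg, target) {
  stopifnot(inherits(seg, "mask_series"), inherits(target, "velocity_field"))
  m <- target$meta
  dt <- dim(target$values)[1:3]
  ds <- dim(seg$occupancy)[1:3]

  # per-axis map: target voxel center -> nearest seg voxel index (NA outside)
  idx <- lapply(1:3, function(ax) {
    x <- axis_coords(dt[ax], m$voxel_size[ax])
    j <- round(x / seg$voxel_size[ax]) + 1L
    j[j < 1L | j > ds[ax]] <- NA_integer_
    j
  })

  # temporal map by normalized cycle time, cyclic nearest
  rr <- m$rr_interval
  tt <- m$frame_times / rr
  seg_cycle <- if (length(seg$frame_times) > 1L)
    max(seg$frame_times) + diff(seg$frame_times[1:2]) else rr
  ts <- seg$frame_times / seg_cycle
  fmap <- vapply(tt, function(t0) {
    d <- abs(ts - t0); d <- pmin(d, 1 - d)
    which.min(d)
  }, integer(1))

  occ <- array(FALSE, c(dt, m$n_frames))
  ii <- idx[[1]]; jj <- idx[[2]]; kk <- idx[[3]]
  ok_i <- !is.na(ii); ok_j <- !is.na(jj); ok_k <- !is.na(kk)
  for (f in seq_len(m$n_frames)) {
    src <- seg$occupancy[, , , fmap[f], drop = FALSE]
    dim(src) <- ds
    occ[ok_i, ok_j, ok_k, f] <- src[ii[ok_i], jj[ok_j], kk[ok_k]]
  }
  mask_series(occ, m$voxel_size, m$frame_times)
}
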