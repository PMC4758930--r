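# Physics core. The pressure-gradient field on the masked LV domain follows
# the incompressible Navier-Stokes momentum balance with body forces excluded:
#   grad p = -rho dv/dt - rho (v . grad) v + mu laplacian(v)   [Pa/m]
# evaluated voxelwise with finite differences that use only in-mask neighbors.
# The global hemodynamic force is the volume integral of grad p over the LV
# per cardiac frame; by the divergence theorem this equals the surface
# pressure force of the blood on its surroundings (action-reaction sign
# convention: F is the force the blood exerts on the wall).

# shift a 3-D array by one voxel along an axis; s = +1 gives A[i+1] at i
shift3 <- function(A, ax, s) {
  d <- dim(A)
  out <- array(NA_real_, d)
  src <- dst <- lapply(d, seq_len)
  if (s == 1L) { dst[[ax]] <- seq_len(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
  else         { dst[[ax]] <- 2:d[ax]; src[[ax]] <- seq_len(d[ax] - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

# first derivative: central where both in-mask neighbors exist, one-sided where
# one exists, NA where none (NA neighbors encode out-of-mask)
fd_first <- function(V, ax, h) {
  Vp <- shift3(V, ax, 1L)
  Vm <- shift3(V, ax, -1L)
  out <- (Vp - Vm) / (2 * h)
  nap <- is.na(Vp); nam <- is.na(Vm)
  i <- nam & !nap
  out[i] <- (Vp[i] - V[i]) / h
  i <- nap & !nam
  out[i] <- (V[i] - Vm[i]) / h
  out[nap & nam] <- NA_real_
  out
}

# second derivative: central where both neighbors exist, else zero
# contribution (one-sided second differences are first-order biased; the
# viscous term is orders of magnitude below the others in vivo)
fd_second <- function(V, ax, h) {
  Vp <- shift3(V, ax, 1L)
  Vm <- shift3(V, ax, -1L)
  out <- (Vp - 2 * V + Vm) / h^2
  out[is.na(out)] <- 0
  out
}

#' Navier-Stokes pressure-gradient field on the masked LV domain
#'
#' Spatial derivatives use second-order central differences restricted to
#' in-mask neighbors, degrading to one-sided at the mask boundary; a voxel
#' with no in-mask neighbor along some axis is marked invalid. The temporal
#' derivative is a cyclic central difference over the cardiac cycle (the last
#' frame precedes the first, as reconstructed by retrospective gating), using
#' each frame's own mask and degrading to one-sided when the voxel leaves the
#' mask in an adjacent frame.
#'
#' @param field A preprocessed \code{\link{velocity_field}}.
#' @param mask A \code{\link{mask_series}} on the same grid and time base.
#' @param include_viscous Include the viscous term (default \code{TRUE}).
#' @return An object of class \code{"pressure_gradient_field"}: \code{values}
#'   \code{[i,j,k,component,frame]} in Pa/m (NA where invalid), logical
#'   \code{valid}, and the term decomposition \code{transient},
#'   \code{convective}, \code{viscous} (same shape; their sum equals
#'   \code{values} wherever valid).
#' @export
pressure_gradient <- function(field, mask, include_viscous = TRUE) {
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "mask_series"))
  d <- dim(field$values)[1:3]
  if (!all(dim(mask$occupancy)[1:3] == d))
    stop("format error: mask grid does not match the velocity grid")
  nf <- field$meta$n_frames
  if (dim(mask$occupancy)[4] != nf)
    stop("format error: mask frame count does not match the velocity field")
  if (nf < 2L)
    stop("domain error: cannot form dv/dt from a single frame")
  rho <- field$meta$rho
  mu <- field$meta$mu
  h <- field$meta$voxel_size * 1e-3   # mm -> m
  tms <- field$meta$frame_times
  rr <- field$meta$rr_interval

  sh <- c(d, 3L, nf)
  transient <- array(NA_real_, sh)
  convective <- array(NA_real_, sh)
  viscous <- array(0, sh)
  valid <- array(FALSE, c(d, nf))

  for (f in seq_len(nf)) {
    m <- mask$occupancy[, , , f]
    fp <- if (f == nf) 1L else f + 1L
    fm <- if (f == 1L) nf else f - 1L
    # cyclic time offsets in seconds
    dt_p <- (tms[fp] - tms[f] + if (f == nf) rr else 0) / 1000
    dt_m <- (tms[f] - tms[fm] + if (f == 1L) rr else 0) / 1000

    vc <- vector("list", 3)      # masked velocity components, this frame
    d1 <- vector("list", 3)      # d1[[c]][[ax]]
    ok_sp <- m
    for (c_i in 1:3) {
      V <- field$values[, , , c_i, f]
      V[!m] <- NA_real_
      vc[[c_i]] <- V
      d1[[c_i]] <- lapply(1:3, function(ax) fd_first(V, ax, h[ax]))
      for (ax in 1:3) ok_sp <- ok_sp & !is.na(d1[[c_i]][[ax]])
      if (include_viscous) {
        lap <- fd_second(V, 1L, h[1]) + fd_second(V, 2L, h[2]) +
          fd_second(V, 3L, h[3])
        lap[!m] <- 0
        viscous[, , , c_i, f] <- mu * lap
      }
    }

    ok_t <- m
    for (c_i in 1:3) {
      Vp <- field$values[, , , c_i, fp]; Vp[!mask$occupancy[, , , fp]] <- NA_real_
      Vm <- field$values[, , , c_i, fm]; Vm[!mask$occupancy[, , , fm]] <- NA_real_
      V <- vc[[c_i]]
      dvdt <- (Vp - Vm) / (dt_p + dt_m)
      nap <- is.na(Vp); nam <- is.na(Vm)
      i <- nam & !nap; dvdt[i] <- (Vp[i] - V[i]) / dt_p
      i <- nap & !nam; dvdt[i] <- (V[i] - Vm[i]) / dt_m
      dvdt[nap & nam] <- NA_real_
      ok_t <- ok_t & !is.na(dvdt)
      transient[, , , c_i, f] <- -rho * dvdt
      adv <- vc[[1]] * d1[[c_i]][[1]] + vc[[2]] * d1[[c_i]][[2]] +
        vc[[3]] * d1[[c_i]][[3]]
      convective[, , , c_i, f] <- -rho * adv
    }
    valid[, , , f] <- ok_sp & ok_t
  }

  values <- transient + convective + viscous
  inval <- rep(!valid, times = 3L)
  dim(inval) <- c(d, nf, 3L)
  inval <- aperm(inval, c(1, 2, 3, 5, 4))
  values[inval] <- NA_real_
  structure(list(values = values, valid = valid, transient = transient,
                 convective = convective, viscous = viscous,
                 meta = field$meta),
            class = "pressure_gradient_field")
}

#' Integrate the pressure-gradient field into the global hemodynamic force
#'
#' \code{F(t) = sum over valid in-mask voxels of grad p * voxel volume} (N).
#' The same integral applied to each term gives the transient, convective and
#' viscous force contributions, which sum to the total at machine precision.
#'
#' @param gradients A \code{"pressure_gradient_field"}.
#' @param mask The \code{\link{mask_series}} used to compute the gradients.
#' @param meta The \code{\link{acquisition_meta}} (voxel size, frame times).
#' @return An object of class \code{"force_trace"}: \code{times} (ms),
#'   \code{F} (n_frames x 3, N), \code{terms} (list of n_frames x 3 matrices),
#'   \code{lv_volume} (m^3 per frame).
#' @export
integrate_force <- function(gradients, mask,
                            meta = gradients$meta) {
  stopifnot(inherits(gradients, "pressure_gradient_field"))
  nf <- meta$n_frames
  vox <- prod(meta$voxel_size) * 1e-9  # mm^3 -> m^3
  F <- matrix(0, nf, 3, dimnames = list(NULL, c("Fx", "Fy", "Fz")))
  terms <- list(transient = F, convective = F, viscous = F)
  lv_volume <- numeric(nf)
  for (f in seq_len(nf)) {
    ok <- gradients$valid[, , , f] & mask$occupancy[, , , f]
    if (!any(ok))
      stop("domain error: frame ", f, " has no valid in-mask voxel")
    for (c_i in 1:3) {
      F[f, c_i] <- sum(gradients$values[, , , c_i, f][ok]) * vox
      terms$transient[f, c_i] <- sum(gradients$transient[, , , c_i, f][ok]) * vox
      terms$convective[f, c_i] <- sum(gradients$convective[, , , c_i, f][ok]) * vox
      terms$viscous[f, c_i] <- sum(gradients$viscous[, , , c_i, f][ok]) * vox
    }
    lv_volume[f] <- sum(mask$occupancy[, , , f]) * vox
  }
  structure(list(times = meta$frame_times, F = F, terms = terms,
                 lv_volume = lv_volume),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  mag <- sqrt(rowSums(x$F^2))
  cat(sprintf("<force_trace> %d frames, |F| peak %.3f N (frame %d), LV volume %.0f-%.0f mL\n",
              nrow(x$F), max(mag), which.max(mag),
              min(x$lv_volume) * 1e6, max(x$lv_volume) * 1e6))
  invisible(x)
}

#' Momentum-balance force oracle
#'
#' An independent route to the global force for closed, essentially inviscid
#' phantoms: \code{F(t) = -rho d/dt integral(v dV)} with the integral over the
#' in-mask voxels and a cyclic central difference in time. Used to
#' cross-validate the pressure-gradient integration path.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param mask A \code{\link{mask_series}} on the same grid.
#' @return n_frames x 3 matrix of forces (N).
#' @export
momentum_force <- function(field, mask) {
  meta <- field$meta
  nf <- meta$n_frames
  vox <- prod(meta$voxel_size) * 1e-9
  mom <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    m <- mask$occupancy[, , , f]
    for (c_i in 1:3) mom[f, c_i] <- sum(field$values[, , , c_i, f][m]) * vox
  }
  tms <- meta$frame_times / 1000
  rr <- meta$rr_interval / 1000
  F <- matrix(0, nf, 3, dimnames = list(NULL, c("Fx", "Fy", "Fz")))
  for (f in seq_len(nf)) {
    fp <- if (f == nf) 1L else f + 1L
    fm <- if (f == 1L) nf else f - 1L
    dt <- (tms[fp] - tms[fm]) %% rr
    if (dt == 0) dt <- rr
    F[f, ] <- -meta$rho * (mom[fp, ] - mom[fm, ]) / dt
  }
  F
}
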