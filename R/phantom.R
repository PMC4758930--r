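# Synthetic 4D flow phantoms with known ground truth.
#
# The LV phantom is a prolate ellipsoid whose volume follows a prescribed
# cycle (EDV -> ESV -> refill in an E and an A wave). The velocity field is a
# spatially smooth bulk component u(t) * w(x,t) -- u(t) composed of compact
# temporal lobes along the anatomical axes, w a cosine apodization that
# vanishes just inside the cavity boundary -- plus confined inflow/outflow
# jets at the MV and AoV that drive the valve-plane speed traces. Because the
# bulk is uniform inside the apodization plateau, its convective volume
# integral cancels (it is the integral of a gradient of a compactly supported
# function), so the global force is dominated by the transient term
# -rho d/dt integral(v dV): the momentum oracle. Amplitudes are tuned by
# construction so the force computed by the pressure-gradient path matches the
# prescribed per-wave force metrics.

#' Analytic validation fields with closed-form forces
#'
#' @param kind \code{"uniform_oscillation"} (ball with spatially uniform
#'   \code{v_x = A sin(2 pi t / T)}; closed-form force
#'   \code{F_x(t) = -rho A (2 pi / T) cos(2 pi t / T) V}),
#'   \code{"poiseuille"} (steady parabolic pipe profile; viscous gradient
#'   \code{-4 mu Vmax / R^2} along the axis), or \code{"rigid_static"}
#'   (zero velocity; zero force).
#' @param grid_n Grid size per axis (default 64).
#' @param n_frames Frames per cycle (default 40; 3 for the steady cases).
#' @param amplitude Peak speed A or Vmax (m/s).
#' @param period Cycle duration T in ms (default 1000).
#' @param volume Ball volume in m^3 for the oscillation case (default 1e-4,
#'   i.e. 100 mL).
#' @param radius Cylinder radius in m for the Poiseuille case (default 0.01).
#' @param rho,mu Blood density and viscosity.
#' @return List with \code{field} (\code{\link{velocity_field}}), \code{mask}
#'   (\code{\link{mask_series}}), and \code{analytic}: the closed-form force
#'   trace \code{F} (n_frames x 3, using the exact voxelized volume), the
#'   continuum force \code{F_continuum} (exact ball volume), and for the
#'   oscillation case \code{F_discrete_time}, the closed form with the cyclic
#'   central-difference temporal factor \code{sin(w dt)/dt} (isolates spatial
#'   from temporal discretization error).
#' @export
analytic_field <- function(kind = c("uniform_oscillation", "poiseuille",
                                    "rigid_static"),
                           grid_n = 64L, n_frames = NULL, amplitude = 0.5,
                           period = 1000, volume = 1e-4, radius = 0.01,
                           rho = 1060, mu = 0.004) {
  kind <- match.arg(kind)
  if (kind == "uniform_oscillation") {
    if (is.null(n_frames)) n_frames <- 40L
    R_mm <- (3 * volume / (4 * pi))^(1 / 3) * 1000
    fov <- 2.4 * R_mm
    h <- fov / grid_n
    meta <- acquisition_meta(venc = 2 * amplitude + 0.1, voxel_size = rep(h, 3),
                             n_frames = n_frames, rr_interval = period,
                             rho = rho, mu = mu)
    ctr <- (grid_n - 1) / 2 * h
    x <- axis_coords(grid_n, h) - ctr
    r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
    ball <- r2 <= R_mm^2
    occ <- array(ball, c(grid_n, grid_n, grid_n, n_frames))
    mask <- mask_series(occ, meta$voxel_size, meta$frame_times)
    vals <- array(0, c(grid_n, grid_n, grid_n, 3L, n_frames))
    w <- 2 * pi / (period / 1000)
    tt <- meta$frame_times / 1000
    for (f in seq_len(n_frames)) vals[, , , 1, f] <- amplitude * sin(w * tt[f])
    field <- velocity_field(vals, meta)
    V_vox <- sum(ball) * prod(meta$voxel_size) * 1e-9
    dt <- period / 1000 / n_frames
    Fx <- function(V, tfac) -rho * amplitude * tfac * cos(w * tt) * V
    mkF <- function(fx) cbind(Fx = fx, Fy = 0, Fz = 0)
    analytic <- list(F = mkF(Fx(V_vox, w)),
                     F_continuum = mkF(Fx(volume, w)),
                     F_discrete_time = mkF(Fx(V_vox, sin(w * dt) / dt)),
                     volume_voxelized = V_vox)
    return(list(field = field, mask = mask, analytic = analytic))
  }
  if (kind == "poiseuille") {
    if (is.null(n_frames)) n_frames <- 3L
    R_mm <- radius * 1000
    h <- 2.4 * R_mm / grid_n
    nz <- max(8L, grid_n %/% 3L)
    meta <- acquisition_meta(venc = amplitude + 0.1, voxel_size = rep(h, 3),
                             n_frames = n_frames, rr_interval = period,
                             rho = rho, mu = mu)
    ctr <- (grid_n - 1) / 2 * h
    x <- axis_coords(grid_n, h) - ctr
    r2 <- outer(x^2, x^2, "+")
    vz2d <- amplitude * (1 - r2 / R_mm^2)   # parabolic, negative outside R
    inside <- r2 <= R_mm^2
    vals <- array(0, c(grid_n, grid_n, nz, 3L, n_frames))
    occ <- array(FALSE, c(grid_n, grid_n, nz, n_frames))
    for (f in seq_len(n_frames)) {
      for (k in seq_len(nz)) {
        vals[, , k, 3, f] <- vz2d
        occ[, , k, f] <- inside
      }
    }
    mask <- mask_series(occ, meta$voxel_size, meta$frame_times)
    field <- velocity_field(vals, meta)
    V_vox <- sum(inside) * nz * prod(meta$voxel_size) * 1e-9
    gz <- -4 * mu * amplitude / radius^2
    analytic <- list(F = cbind(Fx = 0, Fy = 0, Fz = rep(gz * V_vox, n_frames)),
                     gradient_z = gz, volume_voxelized = V_vox)
    return(list(field = field, mask = mask, analytic = analytic))
  }
  # rigid_static
  if (is.null(n_frames)) n_frames <- 4L
  meta <- acquisition_meta(venc = 1, voxel_size = rep(2, 3),
                           n_frames = n_frames, rr_interval = period,
                           rho = rho, mu = mu)
  gn <- max(grid_n, 8L)
  ctr <- (gn - 1) / 2 * 2
  x <- axis_coords(gn, 2) - ctr
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  ball <- r2 <= (0.4 * gn * 2)^2
  occ <- array(ball, c(gn, gn, gn, n_frames))
  field <- velocity_field(array(0, c(gn, gn, gn, 3L, n_frames)), meta)
  mask <- mask_series(occ, meta$voxel_size, meta$frame_times)
  list(field = field, mask = mask,
       analytic = list(F = matrix(0, n_frames, 3,
                                  dimnames = list(NULL, c("Fx", "Fy", "Fz")))))
}

# --- LV phantom ---------------------------------------------------------

#' Specification of an LV phantom subject
#'
#' @param edv End-diastolic volume, mL.
#' @param si Sphericity index (basal diameter / long-axis length); with
#'   \code{edv} it fixes the prolate-ellipsoid geometry.
#' @param ef Ejection fraction (fraction, e.g. 0.61); fixes ESV.
#' @param ratio_e,ratio_a Target SAx-max/LAx-max force ratios per wave.
#' @param mean_sax_e,mean_sax_a Target time-averaged SAx-plane force (N) per
#'   wave.
#' @param n_frames,rr_interval Velocity frames per cycle and cycle length
#'   (ms).
#' @param voxel_size Velocity voxel size, mm (scalar or length 3).
#' @param seg_voxel_size,seg_frames Segmentation grid spacing (mm) and frame
#'   count (the morphology time base).
#' @param jet_e,jet_a,jet_sys Peak jet speeds (m/s) at the MV (E, A) and AoV
#'   (systole).
#' @param sys_peak_force Peak systolic long-axis force (N).
#' @param e_fill_frac Fraction of the stroke volume refilled during the
#'   E-wave.
#' @param noise_sd Gaussian velocity noise SD (m/s); 0 disables.
#' @param background_amp RMS amplitude (m/s) of the injected degree-4
#'   background offset; 0 disables.
#' @param wrap Inject VENC aliasing (values stored modulo \code{2*venc}).
#' @param venc Velocity-encoding limit, m/s.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(edv = 137, si = 0.56, ef = 0.61,
                         ratio_e = 0.23, ratio_a = 0.26,
                         mean_sax_e = 0.032, mean_sax_a = 0.034,
                         n_frames = 40L, rr_interval = 1000,
                         voxel_size = 3, seg_voxel_size = 1.5,
                         seg_frames = 30L,
                         jet_e = 0.85, jet_a = 0.5, jet_sys = 0.9,
                         sys_peak_force = 0.3, e_fill_frac = 0.7,
                         noise_sd = 0, background_amp = 0, wrap = FALSE,
                         venc = 1.0) {
  if (edv <= 0 || ef <= 0 || ef >= 1) stop("spec error: need edv > 0, 0 < ef < 1")
  if (si <= 0 || si > 1.5) stop("spec error: implausible sphericity index")
  if (ratio_e <= 0 || ratio_a <= 0 || mean_sax_e <= 0 || mean_sax_a <= 0)
    stop("spec error: force targets must be positive")
  if (max(jet_e, jet_a, jet_sys) > 2 * venc)
    stop("spec error: infeasible jets (speed > 2*venc cannot be unwrapped)")
  structure(as.list(environment()), class = "phantom_spec")
}

# raised-cosine lobe on [t0, t1] with warp gamma (peak at u = 0.5^(1/gamma))
lobe <- function(t, t0, t1, gamma = 1) {
  u <- (t - t0) / (t1 - t0)
  out <- numeric(length(t))
  i <- u > 0 & u < 1
  out[i] <- sin(pi * u[i]^gamma)^2
  out
}

# asymmetric velocity lobe: cosine rise over [0, rise], faster cosine fall
# over [rise, rise + fall], zero after. The deceleration (apex-directed force)
# peak is narrower and taller than the acceleration peak and sits at
# u = rise + fall/2, placing the force peak after the velocity peak as seen
# in vivo.
asym_lobe <- function(t, t0, t1, rise = 0.5, fall = 0.3) {
  u <- (t - t0) / (t1 - t0)
  out <- numeric(length(t))
  i <- u > 0 & u < rise
  out[i] <- sin(pi / 2 * u[i] / rise)^2
  j <- u >= rise & u < rise + fall
  out[j] <- cos(pi / 2 * (u[j] - rise) / fall)^2
  out
}

# cosine ramp 0 -> 1 on [t0, t1]
cramp <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  (1 - cos(pi * u)) / 2
}

# normalized volume waveform nu(t) (1 at end-diastole); times in ms
vol_waveform <- function(t, windows, esvf, e_fill_frac) {
  eject <- 1 - (1 - esvf) * cramp(t, windows$eject[1], windows$eject[2])
  e_fill <- e_fill_frac * (1 - esvf) * cramp(t, windows$e[1], windows$e[2])
  a_fill <- (1 - e_fill_frac) * (1 - esvf) * cramp(t, windows$a[1], windows$a[2])
  eject + e_fill + a_fill
}

# ellipsoid occupancy and apodization on a grid; returns list(occ, w)
ellipsoid_fields <- function(dims, h, center, semi, apod = TRUE,
                             r0 = 0.70, r1 = 0.92) {
  x <- axis_coords(dims[1], h[1]) - center[1]
  y <- axis_coords(dims[2], h[2]) - center[2]
  z <- axis_coords(dims[3], h[3]) - center[3]
  r2 <- outer(outer((x / semi[1])^2, (y / semi[2])^2, "+"), (z / semi[3])^2, "+")
  occ <- r2 <= 1
  w <- NULL
  if (apod) {
    r <- sqrt(r2)
    w <- array(0, dims)
    w[r <= r0] <- 1
    i <- r > r0 & r < r1
    w[i] <- cos(pi / 2 * (r[i] - r0) / (r1 - r0))^2
  }
  list(occ = occ, w = w)
}

# confined jet: cylinder from `origin` along unit `dir`, axial extent
# [s0, s1] mm, radius r_jet mm, cosine-squared apodization both ways
jet_profile <- function(dims, h, origin, dir, s0, s1, r_jet) {
  x <- axis_coords(dims[1], h[1]) - origin[1]
  y <- axis_coords(dims[2], h[2]) - origin[2]
  z <- axis_coords(dims[3], h[3]) - origin[3]
  X <- array(rep(x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  s <- X * dir[1] + Y * dir[2] + Z * dir[3]
  r2 <- (X - s * dir[1])^2 + (Y - s * dir[2])^2 + (Z - s * dir[3])^2
  prof <- array(0, dims)
  i <- s >= s0 & s <= s1 & r2 <= r_jet^2
  ax <- cos(pi / 2 * (2 * (s[i] - s0) / (s1 - s0) - 1))^2
  rad <- cos(pi / 2 * sqrt(r2[i]) / r_jet)^2
  prof[i] <- ax * rad
  prof
}

#' Generate a synthetic LV phantom subject
#'
#' Builds the moving ellipsoidal mask, the landmark set, the morphology-grid
#' segmentation series, and the velocity field (bulk + jets), then calibrates
#' the bulk amplitudes so the pressure-gradient force metrics match the spec's
#' targets (two fixed-point iterations on the noiseless field). Acquisition
#' artifacts (noise, background offset, aliasing) are injected afterwards if
#' the spec enables them.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param calibrate Tune bulk amplitudes against the package's own force
#'   computation (default \code{TRUE}); with \code{FALSE} the analytic
#'   waveform-based amplitudes are used directly.
#' @return A list: \code{velocity} (observed field, artifacts included),
#'   \code{velocity_clean}, \code{seg} (segmentation on its own 30-frame
#'   grid), \code{mask} (resampled to the velocity grid), \code{landmarks},
#'   \code{covariates} (\code{si}, \code{edv}, \code{ef}), and \code{truth}:
#'   prescribed \code{phases}, \code{targets}, the momentum-oracle force
#'   \code{F_momentum}, and the prescribed \code{edv}.
#' @export
lv_phantom <- function(spec, calibrate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_frames
  rr <- spec$rr_interval
  h <- rep(spec$voxel_size, length.out = 3)
  hs <- rep(spec$seg_voxel_size, length.out = 3)

  # geometry: prolate ellipsoid from EDV and sphericity index
  edv_mm3 <- spec$edv * 1000
  a_semi <- (3 * edv_mm3 / (4 * pi * spec$si^2))^(1 / 3)
  b_semi <- spec$si * a_semi
  pad <- 13
  fov <- c(2 * (b_semi + pad), 2 * (b_semi + pad), 2 * (a_semi + pad))
  dims <- as.integer(ceiling(fov / h))
  ctr0 <- (dims - 1) / 2 * h
  semi0 <- c(b_semi, b_semi, a_semi)

  # frame windows (1-based) and times
  f_t <- (seq_len(n) - 1) * rr / n
  idx <- function(fr) round(fr / 40 * n)
  win_f <- list(eject = c(idx(2), idx(15)), e = c(idx(16), idx(27)),
                a = c(idx(31), 40 / 40 * n + 1))
  windows <- lapply(win_f, function(fr) (fr - 1) * rr / n)
  truth_phases <- phase_map(systole = seq_len(idx(15)),
                            e_wave = idx(16):idx(26),
                            diastasis = idx(27):idx(30),
                            a_wave = idx(31):n, n_frames = n)
  esvf <- 1 - spec$ef
  nu <- vol_waveform(f_t, windows, esvf, spec$e_fill_frac)

  # calibrate the end-diastolic scale so the voxelized mask volume matches the
  # prescribed EDV (plain analytic scaling leaves O(0.5 mL) voxelization error);
  # the end-diastolic ellipsoid sits at the grid center regardless of scale
  cnt_target <- edv_mm3 / prod(h)
  cnt <- function(s, dz) sum(ellipsoid_fields(dims, h, ctr0 + c(0, 0, dz),
                                              semi0 * s, apod = FALSE)$occ)
  # occupancy counts move in integer jumps with the scale; sub-voxel axial
  # shifts of the whole ventricle change the voxelization phase and let the
  # bisection land within the 2-voxel tolerance
  best <- NULL
  for (dz in c(0, 0.25, 0.5, 0.75) * h[3]) {
    lo <- 0.9; hi <- 1.1
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (cnt(mid, dz) < cnt_target) lo <- mid else hi <- mid
    }
    for (s in c(lo, hi)) {
      miss <- abs(cnt(s, dz) - cnt_target)
      if (is.null(best) || miss < best$miss) best <- list(s = s, dz = dz,
                                                          miss = miss)
    }
    if (best$miss <= 1) break
  }
  s_ed2 <- best$s
  ctr0 <- ctr0 + c(0, 0, best$dz)
  # the base plane stays fixed over the cycle; the apex does the moving
  z_base <- ctr0[3] + a_semi * s_ed2
  center_at <- function(lam) c(ctr0[1], ctr0[2], z_base - a_semi * lam)
  semi_at <- function(lam) semi0 * lam
  lam <- s_ed2 * nu^(1 / 3)

  # landmarks at end-diastole (base plane at high z, apex at low z)
  ed_center <- center_at(lam[1])
  ed_semi <- semi_at(lam[1])
  on_base <- function(frac_x) {
    dx <- frac_x * ed_semi[1]
    c(ed_center[1] + dx, ed_center[2],
      ed_center[3] + ed_semi[3] * sqrt(1 - frac_x^2))
  }
  landmarks <- lv_landmarks(apex = ed_center - c(0, 0, ed_semi[3]),
                            mv_center = on_base(-0.35),
                            aov_center = on_base(0.45))
  axes <- build_axes(landmarks)

  # per-frame occupancy and apodization on the velocity grid
  occ <- array(FALSE, c(dims, n))
  w_apod <- vector("list", n)
  for (f in seq_len(n)) {
    ef_f <- ellipsoid_fields(dims, h, center_at(lam[f]), semi_at(lam[f]))
    occ[, , , f] <- ef_f$occ
    w_apod[[f]] <- ef_f$w
  }
  meta <- acquisition_meta(venc = spec$venc, voxel_size = h, n_frames = n,
                           rr_interval = rr)
  mask <- mask_series(occ, h, meta$frame_times)
  W_int <- vapply(w_apod, sum, numeric(1)) * prod(h) * 1e-9  # integral of w, m^3

  # segmentation series on its own (morphology) grid and 30-frame time base
  segn <- spec$seg_frames
  seg_t <- (seq_len(segn) - 1) * rr / segn
  nu_seg <- vol_waveform(seg_t, windows, esvf, spec$e_fill_frac)
  lam_seg <- s_ed2 * nu_seg^(1 / 3)
  seg_dims <- as.integer(ceiling(fov / hs))
  # seg grid shares the origin; same physical center
  seg_occ <- array(FALSE, c(seg_dims, segn))
  for (f in seq_len(segn)) {
    seg_occ[, , , f] <- ellipsoid_fields(seg_dims, hs, center_at(lam_seg[f]),
                                         semi_at(lam_seg[f]), apod = FALSE)$occ
  }
  seg <- mask_series(seg_occ, hs, seg_t)

  # jets (amplitude-independent spatial profiles x temporal lobes)
  jet_dir_mv <- normalize3(landmarks$apex - landmarks$mv_center)
  jet_dir_ao <- normalize3(landmarks$aov_center - ed_center)
  prof_mv <- jet_profile(dims, h, landmarks$mv_center, jet_dir_mv,
                         s0 = -8, s1 = 0.55 * a_semi, r_jet = 7)
  prof_ao <- jet_profile(dims, h, landmarks$aov_center, jet_dir_ao,
                         s0 = -0.4 * a_semi, s1 = 12, r_jet = 6)
  lobe_e <- lobe(f_t, windows$e[1], windows$e[2])
  lobe_a <- lobe(f_t, windows$a[1], windows$a[2])
  lobe_s <- lobe(f_t, windows$eject[1], windows$eject[2])

  # bulk waveforms (unit amplitudes); force follows -rho d/dt (u W)
  shapes <- list(
    long_e = asym_lobe(f_t, windows$e[1], windows$e[2]),
    long_a = asym_lobe(f_t, windows$a[1], windows$a[2]),
    long_s = -lobe(f_t, windows$eject[1], windows$eject[2]),
    s1_e = lobe(f_t, windows$e[1], windows$e[2]),
    s1_a = lobe(f_t, windows$a[1], windows$a[2]),
    s2_e = lobe(f_t, windows$e[1], windows$e[2], gamma = 0.65),
    s2_a = lobe(f_t, windows$a[1], windows$a[2], gamma = 0.65))

  # waveform-level force preview for initial amplitudes
  rho <- meta$rho
  wave_force <- function(sh) {
    mom <- rho * sh * W_int
    n <- length(mom)
    (-(mom[c(2:n, 1)] - mom[c(n, 1:(n - 1))])) / (2 * rr / n / 1000)
  }
  wf_s1e <- wave_force(shapes$s1_e)
  wf_s1a <- wave_force(shapes$s1_a)
  wf_le <- wave_force(shapes$long_e)
  wf_la <- wave_force(shapes$long_a)
  wf_ls <- wave_force(shapes$long_s)
  ew <- truth_phases$e_wave; aw <- truth_phases$a_wave
  amps <- list(
    b_e = spec$mean_sax_e / mean(abs(wf_s1e[ew])),
    b_a = spec$mean_sax_a / mean(abs(wf_s1a[aw])))
  amps$a_e <- amps$b_e * max(abs(wf_s1e[ew])) / spec$ratio_e /
    max(abs(wf_le[ew]))
  amps$a_a <- amps$b_a * max(abs(wf_s1a[aw])) / spec$ratio_a /
    max(abs(wf_la[aw]))
  amps$a_s <- spec$sys_peak_force / max(abs(wf_ls))

  build_field <- function(amps) {
    u_long <- amps$a_e * shapes$long_e + amps$a_a * shapes$long_a +
      amps$a_s * shapes$long_s
    u_s1 <- amps$b_e * shapes$s1_e + amps$b_a * shapes$s1_a
    u_s2 <- 0.35 * (amps$b_e * shapes$s2_e + amps$b_a * shapes$s2_a)
    # grid-axis velocity per frame
    U <- cbind(u_long, u_s1, u_s2) %*%
      rbind(axes$e_long, axes$e_sax1, axes$e_sax2)
    vals <- array(0, c(dims, 3L, n))
    for (f in seq_len(n)) {
      jet <- spec$jet_e * lobe_e[f] * prof_mv + spec$jet_a * lobe_a[f] * prof_mv
      jet_ao <- spec$jet_sys * lobe_s[f] * prof_ao
      for (c_i in 1:3) {
        vals[, , , c_i, f] <- w_apod[[f]] * U[f, c_i] +
          jet * jet_dir_mv[c_i] + jet_ao * jet_dir_ao[c_i]
      }
    }
    velocity_field(vals, meta)
  }

  # measure with the same phase windows the pipeline will detect (detected
  # windows run a frame wider than the prescribed ones; calibrating against
  # the prescribed windows would bias the time-averaged SAx force)
  measure <- function(field) {
    phs <- tryCatch(detect_phases(extract_speed_traces(field, landmarks),
                                  meta),
                    error = function(e) truth_phases,
                    warning = function(w) truth_phases)
    pg <- pressure_gradient(field, mask)
    tr <- integrate_force(pg, mask, meta)
    pr <- project_force(tr, axes)
    list(ratio_e = sax_lax_ratio(pr, phs, "E"),
         ratio_a = sax_lax_ratio(pr, phs, "A"),
         mean_sax_e = mean_sax_force(pr, phs, "E"),
         mean_sax_a = mean_sax_force(pr, phs, "A"))
  }

  field <- build_field(amps)
  if (calibrate) {
    for (it in 1:2) {
      m <- measure(field)
      sb_e <- spec$mean_sax_e / m$mean_sax_e
      sb_a <- spec$mean_sax_a / m$mean_sax_a
      amps$b_e <- amps$b_e * sb_e
      amps$b_a <- amps$b_a * sb_a
      amps$a_e <- amps$a_e * sb_e * m$ratio_e / spec$ratio_e
      amps$a_a <- amps$a_a * sb_a * m$ratio_a / spec$ratio_a
      field <- build_field(amps)
    }
  }

  truth <- list(phases = truth_phases,
                targets = list(ratio_e = spec$ratio_e, ratio_a = spec$ratio_a,
                               mean_sax_e = spec$mean_sax_e,
                               mean_sax_a = spec$mean_sax_a),
                F_momentum = momentum_force(field, mask),
                edv = spec$edv, amplitudes = amps)

  observed <- inject_artifacts(field, noise_sd = spec$noise_sd,
                               background_amp = spec$background_amp,
                               wrap = spec$wrap)
  list(velocity = observed, velocity_clean = field, seg = seg, mask = mask,
       landmarks = landmarks,
       covariates = list(si = spec$si, edv = spec$edv, ef = spec$ef),
       truth = truth, spec = spec)
}

#' Inject acquisition artifacts into a velocity field
#'
#' Adds Gaussian velocity noise, then a smooth degree-4 polynomial background
#' offset per component, then (optionally) aliases stored values into
#' \code{[-venc, venc)} the way the phase reconstruction would. Uses the
#' current RNG state.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param noise_sd Gaussian noise SD in m/s (0 = none).
#' @param background_amp RMS amplitude of the random background polynomial in
#'   m/s (0 = none).
#' @param wrap Apply VENC aliasing.
#' @return The corrupted \code{\link{velocity_field}}.
#' @export
inject_artifacts <- function(field, noise_sd = 0, background_amp = 0,
                             wrap = FALSE) {
  if (noise_sd == 0 && background_amp == 0 && !wrap) return(field)
  v <- field$values
  d <- dim(v)[1:3]
  nf <- dim(v)[5]
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  if (background_amp > 0) {
    coords <- scaled_coords(d, field$meta$voxel_size)
    des <- poly_design(coords, 4)
    deg <- des$exponents$a + des$exponents$b + des$exponents$c
    for (c_i in 1:3) {
      beta <- stats::rnorm(ncol(des$X)) * 0.5^deg
      off <- des$X %*% beta
      off <- off * (background_amp / sqrt(mean(off^2)))
      v[, , , c_i, ] <- v[, , , c_i, ] + as.numeric(off)
    }
  }
  if (wrap) v <- alias_velocity(v, field$meta$venc)
  field$values <- v
  field
}
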