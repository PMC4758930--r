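# Small in-code fixtures shared across tests.

# minimal metadata for a tiny grid
tiny_meta <- function(n_frames = 5L, venc = 1, voxel = 2, rr = 1000,
                      mu = 0.004) {
  acquisition_meta(venc = venc, voxel_size = rep(voxel, 3),
                   n_frames = n_frames, rr_interval = rr, mu = mu)
}

# velocity field with constant value per (component, frame) from a function
# vfun(comp, frame) -> scalar, on a dims grid
uniform_velocity <- function(dims = c(6, 6, 6), vfun = function(c, f) 0,
                             meta = tiny_meta()) {
  vals <- array(0, c(dims, 3L, meta$n_frames))
  for (c_i in 1:3) for (f in seq_len(meta$n_frames))
    vals[, , , c_i, f] <- vfun(c_i, f)
  velocity_field(vals, meta)
}

# all-occupied mask matching a velocity field
full_mask <- function(field) {
  d <- dim(field$values)
  mask_series(array(TRUE, c(d[1:3], d[5])), field$meta$voxel_size,
              field$meta$frame_times)
}

# a calibrated noiseless healthy-like phantom, cached per session (several
# tests reuse it; generation is the expensive part)
cached_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) {
      set.seed(42)
      ph <<- lv_phantom(phantom_spec())
    }
    ph
  }
})

# surface-quadrature oracle: closed integral of p * n over a sphere of radius
# R (m) for p(x) = alpha * x, by lat-long midpoint quadrature (independent of
# the volume-integration path)
surface_pressure_integral <- function(alpha, R, n_theta = 400, n_phi = 800) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dth <- pi / n_theta; dphi <- 2 * pi / n_phi
  Fx <- 0
  for (t_i in th) {
    nx <- sin(t_i) * cos(phi)
    p <- alpha * R * nx
    Fx <- Fx + sum(p * nx) * R^2 * sin(t_i) * dth * dphi
  }
  Fx  # y and z components vanish by symmetry
}

# numerical-integration oracle for the two-tailed t-distribution p-value,
# independent of stats::pt: integrates the t density by quadrature
p_oracle <- function(t_stat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
}
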