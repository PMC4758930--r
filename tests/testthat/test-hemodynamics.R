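test_that("uniform oscillation reproduces the closed-form transient force", {
  af <- analytic_field("uniform_oscillation", grid_n = 32L)
  pg <- pressure_gradient(af$field, af$mask)
  tr <- integrate_force(pg, af$mask)
  # convective and viscous vanish identically for a spatially uniform field
  expect_equal(max(abs(tr$terms$convective)), 0)
  expect_equal(max(abs(tr$terms$viscous)), 0)
  # the cyclic central difference gives exactly the sinc-factored closed form
  expect_equal(tr$F[, 1], unname(af$analytic$F_discrete_time[, 1]),
               tolerance = 1e-12)
  # and the continuum closed form -rho A (2 pi / T) cos * V at the peak to 2%
  expect_lt(abs(tr$F[1, 1] - af$analytic$F_continuum[1, 1]) /
              abs(af$analytic$F_continuum[1, 1]), 0.02)
  expect_equal(unname(af$analytic$F_continuum[1, 1]), -0.333,
               tolerance = 2e-3)
  expect_equal(max(abs(tr$F[, 2:3])), 0)
})

test_that("a rigid static fluid produces exactly zero force in every term", {
  af <- analytic_field("rigid_static", grid_n = 12L)
  pg <- pressure_gradient(af$field, af$mask)
  tr <- integrate_force(pg, af$mask)
  expect_equal(max(abs(tr$F)), 0)
  expect_equal(max(abs(tr$terms$transient)), 0)
  expect_equal(max(abs(tr$terms$convective)), 0)
  expect_equal(max(abs(tr$terms$viscous)), 0)
})

test_that("Poiseuille flow recovers the viscous pressure gradient in the interior", {
  po <- analytic_field("poiseuille", grid_n = 32L, amplitude = 1)
  pg <- pressure_gradient(po$field, po$mask)
  # central second differences are exact for the parabolic profile: every
  # interior voxel must carry exactly -4 mu Vmax / R^2 = -160 Pa/m
  d <- dim(po$field$values)
  ctr <- (d[1] + 1) / 2
  expect_equal(pg$values[round(ctr), round(ctr), 4, 3, 1], -160,
               tolerance = 1e-9)
  expect_equal(pg$transient[round(ctr), round(ctr), 4, 3, 1], 0)
  expect_equal(pg$convective[round(ctr), round(ctr), 4, 3, 1], 0)
  # interior voxels (one voxel in from the wall) all agree
  interior <- po$mask$occupancy[, , , 1]
  for (ax in 1:2) for (s in c(-1, 1)) {
    nb <- lvforce:::shift3(interior * 1, ax, s); nb[is.na(nb)] <- 0
    interior <- interior & nb > 0
  }
  vals <- pg$values[, , 4, 3, 1][interior[, , 4]]
  expect_equal(max(abs(vals + 160)), 0, tolerance = 1e-8)
})

test_that("force integration is the sum of gradient times voxel volume", {
  # hand-built constant gradient: F = grad p * V exactly
  meta <- tiny_meta(n_frames = 2L, voxel = 2)
  dims <- c(5, 5, 5)
  vals <- array(0, c(dims, 3, 2))
  vals[, , , 1, ] <- -3330.1
  pgf <- structure(list(values = vals, valid = array(TRUE, c(dims, 2)),
                        transient = vals,
                        convective = array(0, c(dims, 3, 2)),
                        viscous = array(0, c(dims, 3, 2)), meta = meta),
                   class = "pressure_gradient_field")
  occ <- array(TRUE, c(dims, 2))
  mask <- mask_series(occ, meta$voxel_size, meta$frame_times)
  tr <- integrate_force(pgf, mask, meta)
  V <- 125 * 8e-9
  expect_equal(unname(tr$F[1, 1]), -3330.1 * V, tolerance = 1e-12)
  expect_equal(tr$lv_volume[1], V)
  # scaled to 100 mL this is the worked magnitude -0.333 N
  expect_equal(-3330.1 * 1e-4, -0.333, tolerance = 1e-4)
})

test_that("volume integral of grad p matches the surface-pressure oracle", {
  # p = alpha x over a ball: integral of grad p dV vs closed surface integral
  alpha <- 1000  # Pa/m
  af <- analytic_field("uniform_oscillation", grid_n = 32L, n_frames = 2L)
  d <- dim(af$field$values)[1:3]
  vals <- array(0, c(d, 3, 2))
  vals[, , , 1, ] <- alpha
  pgf <- structure(list(values = vals, valid = array(TRUE, c(d, 2)),
                        transient = vals, convective = array(0, c(d, 3, 2)),
                        viscous = array(0, c(d, 3, 2)),
                        meta = af$field$meta),
                   class = "pressure_gradient_field")
  m2 <- mask_series(af$mask$occupancy[, , , 1:2, drop = FALSE],
                    af$mask$voxel_size, af$field$meta$frame_times[1:2])
  tr <- integrate_force(pgf, m2, af$field$meta)
  R <- (3 * 1e-4 / (4 * pi))^(1 / 3)
  Fx_surface <- surface_pressure_integral(alpha, R)
  expect_lt(abs(tr$F[1, 1] - Fx_surface) / abs(Fx_surface), 0.01)
})

test_that("the total force equals the sum of its term decomposition", {
  ph <- cached_phantom()
  pg <- pressure_gradient(ph$velocity_clean, ph$mask)
  ok <- pg$valid
  recon <- pg$transient + pg$convective + pg$viscous
  diff <- abs(pg$values - recon)
  expect_lt(max(diff[!is.na(diff)]), 1e-9)
  tr <- integrate_force(pg, ph$mask)
  total_from_terms <- tr$terms$transient + tr$terms$convective +
    tr$terms$viscous
  expect_equal(tr$F, total_from_terms, tolerance = 1e-12)
})

test_that("temporal refinement converges at second order", {
  errs <- vapply(c(10L, 20L, 40L), function(nf) {
    af <- analytic_field("uniform_oscillation", grid_n = 16L, n_frames = nf)
    pg <- pressure_gradient(af$field, af$mask)
    tr <- integrate_force(pg, af$mask)
    pk <- which.max(abs(af$analytic$F[, 1]))
    abs(tr$F[pk, 1] - af$analytic$F[pk, 1]) / abs(af$analytic$F[pk, 1])
  }, numeric(1))
  # halving dt divides the sinc-factor error by ~4
  expect_gt(errs[1] / errs[2], 3.5)
  expect_lt(errs[1] / errs[2], 4.5)
  expect_gt(errs[2] / errs[3], 3.5)
  expect_lt(errs[2] / errs[3], 4.5)
})

test_that("degenerate inputs raise domain errors", {
  meta1 <- acquisition_meta(1, rep(2, 3), 1L, 1000)
  f1 <- velocity_field(array(0, c(4, 4, 4, 3, 1)), meta1)
  m1 <- mask_series(array(TRUE, c(4, 4, 4, 1)), rep(2, 3), 0)
  expect_error(pressure_gradient(f1, m1), "single frame")

  # isolated voxels (no in-mask neighbors) are invalid -> integration errors
  meta2 <- tiny_meta(n_frames = 2L)
  f2 <- uniform_velocity(c(5, 5, 5), function(c, f) 0.1, meta2)
  occ <- array(FALSE, c(5, 5, 5, 2))
  occ[3, 3, 3, ] <- TRUE
  m2 <- mask_series(occ, meta2$voxel_size, meta2$frame_times)
  pg <- pressure_gradient(f2, m2)
  expect_false(any(pg$valid))
  expect_error(integrate_force(pg, m2, meta2), "no valid")
})
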