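# DP oracle for temporal unwrapping: exact minimization of the summed
# temporal jumps over per-frame wrap integers in {-2..2}, anchored at the
# reference frame (wrap 0), along the cyclic frame order the estimator uses.
dp_unwrap_oracle <- function(stored, venc, ref) {
  n <- length(stored)
  ks <- -2:2
  ord <- c(ref, ((ref - 1 + seq_len(n - 1)) %% n) + 1)
  cost <- ifelse(ks == 0, 0, Inf)          # ref frame fixed at k = 0
  choice <- matrix(NA_integer_, n, length(ks))
  for (step in 2:n) {
    f <- ord[step]; fp <- ord[step - 1]
    new_cost <- rep(Inf, length(ks))
    for (a in seq_along(ks)) {
      v <- stored[f] + 2 * venc * ks[a]
      trans <- cost + abs(v - (stored[fp] + 2 * venc * ks))
      new_cost[a] <- min(trans)
      choice[step, a] <- which.min(trans)
    }
    cost <- new_cost
  }
  k <- integer(n)
  a <- which.min(cost)
  for (step in n:2) {
    k[ord[step]] <- ks[a]
    a <- choice[step, a]
  }
  stored + 2 * venc * k
}

as_single_voxel_field <- function(series, venc) {
  nf <- length(series)
  meta <- acquisition_meta(venc, rep(2, 3), nf, 1000)
  vals <- array(0, c(2, 2, 2, 3, nf))
  vals[1, 1, 1, 1, ] <- series
  velocity_field(vals, meta)
}

test_that("unwrapping restores aliased velocities", {
  # textbook case: true 1.3 m/s at venc 1.0 stored as -0.7
  truth <- c(0.1, 1.0, 1.3, 1.0, 0.1)
  stored <- lvforce:::alias_velocity(truth, 1)
  expect_equal(stored[3], -0.7)
  f <- as_single_voxel_field(stored, 1)
  out <- unwrap_velocity(f)
  expect_equal(out$values[1, 1, 1, 1, ], truth, tolerance = 1e-12)

  # smooth sub-venc series is untouched
  smooth <- 0.4 * sin(2 * pi * (0:9) / 10)
  f2 <- as_single_voxel_field(smooth, 1)
  expect_equal(unwrap_velocity(f2)$values, f2$values, tolerance = 1e-15)
})

test_that("unwrapping matches the exhaustive wrap-integer oracle", {
  set.seed(3)
  venc <- 1
  for (rep_i in 1:20) {
    nf <- 12L
    # smooth truth with temporal jumps below venc, amplitude up to ~1.8*venc
    truth <- cumsum(runif(nf, -0.45, 0.45))
    truth <- truth - mean(truth)
    truth <- truth / max(abs(truth), 1) * runif(1, 0.8, 1.8)
    # enforce cyclic smoothness (retrospective gating wraps around)
    truth <- truth * sin(pi * ((seq_len(nf) - 0.5) / nf))^2
    stored <- lvforce:::alias_velocity(truth, venc)
    f <- as_single_voxel_field(stored, venc)
    out <- unwrap_velocity(f)$values[1, 1, 1, 1, ]
    sm <- apply(abs(f$values), 5, mean)
    ref <- which.min(sm)
    oracle <- dp_unwrap_oracle(stored, venc, ref)
    expect_equal(out, oracle, tolerance = 1e-12)
    expect_equal(out, truth, tolerance = 1e-12)
  }
})

test_that("static-tissue weights follow the Gaussian-in-SD rule", {
  nf <- 6L
  meta <- tiny_meta(n_frames = nf)
  vals <- array(0, c(4, 4, 4, 3, nf))
  vals[1, 1, 1, 1, ] <- 0.3                      # constant -> weight 1
  vals[2, 1, 1, 1, ] <- 0.3 + c(-1, 1)[rep(1:2, 3)] * 0.05  # speed SD = scale
  vals[3, 1, 1, 1, ] <- 0.3 + c(-1, 1)[rep(1:2, 3)] * 0.10  # SD = 2*scale
  w <- static_tissue_weights(velocity_field(vals, meta), scale = 0.05)
  expect_equal(w[1, 1, 1], 1)
  expect_equal(w[2, 1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(w[3, 1, 1], exp(-4), tolerance = 1e-12)
  expect_equal(w[4, 4, 4], 1)                    # zero velocity is static too
})

test_that("phantom blood is down-weighted, static tissue is not", {
  ph <- cached_phantom()
  w <- static_tissue_weights(ph$velocity_clean)
  core <- ph$mask$occupancy[, , , 1] & ph$mask$occupancy[, , , 20]
  expect_lt(mean(w[core]), 0.35)
  outside <- !ph$mask$occupancy[, , , 1]
  expect_gt(mean(w[outside]), 0.9)
})

test_that("background fit recovers an exact degree-4 offset to machine precision", {
  set.seed(5)
  meta <- acquisition_meta(1, rep(4, 3), 3L, 1000)
  dims <- c(9, 9, 9)
  field0 <- velocity_field(array(0, c(dims, 3, 3)), meta)
  coords <- lvforce:::scaled_coords(dims, meta$voxel_size)
  X <- lvforce:::poly_design(coords, 4)$X
  beta_true <- matrix(rnorm(ncol(X) * 3, sd = 0.01), ncol = 3)
  off <- X %*% beta_true
  vals <- field0$values
  for (c_i in 1:3) for (f in 1:3) vals[, , , c_i, f] <- off[, c_i]
  field <- velocity_field(vals, meta)

  model <- fit_background(field, array(1, dims))
  expect_lt(max(abs(model$resid_rms)), 1e-9)
  corrected <- apply_background(field, model)
  expect_lt(max(abs(corrected$values)), 1e-9)

  # refitting the corrected field changes it by < 1e-9 m/s
  model2 <- fit_background(corrected, array(1, dims))
  twice <- apply_background(corrected, model2)
  expect_lt(max(abs(twice$values - corrected$values)), 1e-9)

  # zero offset -> zero model
  model0 <- fit_background(field0, array(1, dims))
  expect_lt(max(abs(eval_background(model0))), 1e-12)
})

test_that("background recovery stays below the noise floor under noise", {
  set.seed(6)
  meta <- acquisition_meta(1, rep(3, 3), 4L, 1000)
  dims <- c(20, 20, 20)
  coords <- lvforce:::scaled_coords(dims, meta$voxel_size)
  X <- lvforce:::poly_design(coords, 4)$X
  beta_true <- matrix(rnorm(ncol(X) * 3, sd = 0.01), ncol = 3)
  off <- X %*% beta_true
  vals <- array(rnorm(prod(dims) * 3 * 4, sd = 0.01), c(dims, 3, 4))
  for (c_i in 1:3) for (f in 1:4)
    vals[, , , c_i, f] <- vals[, , , c_i, f] + off[, c_i]
  field <- velocity_field(vals, meta)
  model <- fit_background(field, array(1, dims))
  est <- eval_background(model)
  rmse <- sqrt(mean((est - array(off, c(dims, 3)))^2))
  expect_lt(rmse, 0.01)
})

test_that("background correction is linear and degenerate fits error", {
  set.seed(8)
  meta <- acquisition_meta(1, rep(4, 3), 2L, 1000)
  dims <- c(8, 8, 8)
  mk <- function(sd) {
    coords <- lvforce:::scaled_coords(dims, meta$voxel_size)
    X <- lvforce:::poly_design(coords, 4)$X
    beta <- matrix(rnorm(ncol(X) * 3, sd = sd), ncol = 3)
    off <- X %*% beta
    vals <- array(0, c(dims, 3, 2))
    for (c_i in 1:3) for (f in 1:2) vals[, , , c_i, f] <- off[, c_i]
    velocity_field(vals, meta)
  }
  fa <- mk(0.01); fb <- mk(0.02)
  both <- fa; both$values <- fa$values + fb$values
  ma <- fit_background(fa, array(1, dims))
  mb <- fit_background(fb, array(1, dims))
  seq_applied <- apply_background(apply_background(both, ma), mb)
  mab <- ma; mab$coefficients <- ma$coefficients + mb$coefficients
  at_once <- apply_background(both, mab)
  expect_equal(seq_applied$values, at_once$values, tolerance = 1e-12)

  w_bad <- array(0, dims); w_bad[1:3, 1, 1] <- 1  # fewer points than terms
  expect_error(fit_background(fa, w_bad), "fit error")
})

test_that("preprocessing is near-identity on an artifact-free phantom", {
  ph <- cached_phantom()
  # unwrapping alone is the exact identity below venc
  unw <- unwrap_velocity(ph$velocity_clean)
  expect_equal(unw$values, ph$velocity_clean$values, tolerance = 1e-15)
  # the soft static mask gives residual weight to slow-moving blood, so the
  # background stage removes a small spurious offset; it must stay well below
  # the acquisition noise floor
  pre <- preprocess_velocity(ph$velocity_clean)
  expect_lt(max(abs(pre$values - ph$velocity_clean$values)), 2e-3)
})

test_that("artifact injection round-trips through preprocessing", {
  ph <- cached_phantom()
  set.seed(9)
  # wraps only (no noise): unwrap restores exactly; jet pushed beyond venc
  spec_hot <- phantom_spec(jet_e = 1.3, wrap = TRUE)
  hot <- lv_phantom(spec_hot, calibrate = FALSE)
  expect_gt(max(abs(hot$velocity_clean$values)), hot$velocity$meta$venc)
  expect_gt(max(abs(hot$velocity_clean$values - hot$velocity$values)), 1)
  restored <- unwrap_velocity(hot$velocity)
  expect_lt(max(abs(restored$values - hot$velocity_clean$values)), 1e-9)

  # noise + background + wraps: corrected force trace close to the clean one
  set.seed(10)
  noisy <- inject_artifacts(ph$velocity_clean, noise_sd = 0.02,
                            background_amp = 0.02, wrap = TRUE)
  pre <- preprocess_velocity(noisy)
  tr_clean <- integrate_force(pressure_gradient(ph$velocity_clean, ph$mask),
                              ph$mask)
  tr_noisy <- integrate_force(pressure_gradient(pre, ph$mask), ph$mask)
  rms_rel <- sqrt(mean((tr_noisy$F - tr_clean$F)^2)) /
    sqrt(mean(tr_clean$F^2))
  expect_lt(rms_rel, 0.05)

  # no-op injection is the identity
  same <- inject_artifacts(ph$velocity_clean, 0, 0, FALSE)
  expect_identical(same$values, ph$velocity_clean$values)
})
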