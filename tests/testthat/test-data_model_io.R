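test_that("acquisition metadata enforces its physical invariants", {
  m <- tiny_meta()
  expect_s3_class(m, "acquisition_meta")
  expect_equal(m$frame_times, seq(0, 800, by = 200))  # uniform default
  expect_error(acquisition_meta(-1, c(3, 3, 3), 40, 1000), "venc")
  expect_error(acquisition_meta(1, c(3, 0, 3), 40, 1000), "voxel_size")
  expect_error(acquisition_meta(1, c(3, 3, 3), 40, 1000,
                                frame_times = rep(0, 40)), "increasing")
  expect_error(acquisition_meta(1, c(3, 3, 3), 2, 1000,
                                frame_times = c(0, 1500)), "increasing")
})

test_that("velocity NIfTI round trip preserves values and converts units", {
  dir <- withr::local_tempdir()
  set.seed(1)
  meta <- tiny_meta(n_frames = 5L)
  vals <- array(rnorm(6 * 6 * 6 * 3 * 5, sd = 0.3), c(6, 6, 6, 3, 5))
  field <- velocity_field(vals, meta)
  paths <- write_velocity(field, dir)
  back <- read_velocity(paths[1:3], paths[4])
  expect_equal(back$values, field$values, tolerance = 1e-12)
  expect_equal(back$meta$venc, 1)
  expect_equal(back$meta$voxel_size, c(2, 2, 2))

  # sidecar declaring cm/s storage and a string venc
  sc <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  sc$venc <- "100 cm/s"
  sc$velocity_unit <- "cm/s"
  jsonlite::write_json(sc, paths[4], auto_unbox = TRUE, digits = NA)
  back2 <- read_velocity(paths[1:3], paths[4])
  expect_equal(back2$meta$venc, 1.0)              # 100 cm/s -> 1 m/s
  expect_equal(back2$values, field$values * 0.01, tolerance = 1e-12)
})

test_that("velocity reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  field <- uniform_velocity(vfun = function(c, f) 0.1 * c)
  paths <- write_velocity(field, dir)
  expect_error(read_velocity(paths[c(1, 2)], paths[4]), "three component")
  file.remove(paths[2])
  expect_error(read_velocity(paths[1:3], paths[4]), "missing")
  # sidecar without venc
  sc <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  sc$venc <- NULL
  jsonlite::write_json(sc, paths[4], auto_unbox = TRUE, digits = NA)
  expect_error(read_sidecar(paths[4]), "venc")
})

test_that("mask resampling matches a brute-force nearest-neighbor oracle", {
  set.seed(7)
  # 6x6x6, 5-frame segmentation on a 3 mm grid; target 8x8x8, 8 frames, 2.2 mm
  seg_occ <- array(runif(6 * 6 * 6 * 5) > 0.4, c(6, 6, 6, 5))
  seg_occ[2, 2, 2, ] <- TRUE  # keep every frame non-empty
  seg <- mask_series(seg_occ, rep(3, 3), seq(0, 800, by = 200))
  meta <- acquisition_meta(1, rep(2.2, 3), 8L, 1000)
  target <- velocity_field(array(0, c(8, 8, 8, 3, 8)), meta)

  got <- resample_mask(seg, target)

  # exhaustive per-voxel oracle
  expected <- array(FALSE, c(8, 8, 8, 8))
  ts <- seg$frame_times / 1000
  tt <- meta$frame_times / 1000
  for (f in 1:8) {
    dcirc <- abs(ts - tt[f]); dcirc <- pmin(dcirc, 1 - dcirc)
    fs <- which.min(dcirc)
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      p <- (c(i, j, k) - 1) * 2.2
      q <- round(p / 3) + 1
      if (all(q >= 1 & q <= 6)) expected[i, j, k, f] <- seg_occ[q[1], q[2], q[3], fs]
    }
  }
  expect_identical(got$occupancy, expected)

  # identity on the same basis, and idempotence
  meta_same <- acquisition_meta(1, rep(3, 3), 5L, 1000)
  target_same <- velocity_field(array(0, c(6, 6, 6, 3, 5)), meta_same)
  same <- resample_mask(seg, target_same)
  expect_identical(same$occupancy, seg$occupancy)
  expect_identical(resample_mask(same, target_same)$occupancy, same$occupancy)
})

test_that("an empty segmentation frame is rejected", {
  occ <- array(TRUE, c(4, 4, 4, 3))
  occ[, , , 2] <- FALSE
  expect_error(mask_series(occ, rep(3, 3), c(0, 333, 667)), "empty frame")
})

test_that("metrics and force-trace CSV export round-trip, phases label every frame once", {
  dir <- withr::local_tempdir()
  rows <- lapply(1:10, function(s)
    structure(list(ratio_e = s / 10, ratio_a = s / 20, mean_sax_e = 0.03,
                   mean_sax_a = 0.03, lax_max_e = 0.2, lax_max_a = 0.1,
                   sax_max_e = 0.05, sax_max_a = 0.04, loop_dir_e = "CCW",
                   loop_dir_a = "CW", peak_lag_e = 25, si = 0.5, edv = 137),
              class = "subject_metrics"))
  p <- write_metrics(rows, file.path(dir, "metrics.csv"))
  back <- read.csv(p)
  expect_equal(nrow(back), 10)
  expect_equal(back$ratio_e, (1:10) / 10)

  phases <- phase_map(1:15, 16:26, 27:30, 31:40, 40L)
  trace <- structure(list(times = seq(0, 975, by = 25),
                          F = matrix(rnorm(120), 40, 3),
                          terms = NULL, lv_volume = rep(1e-4, 40)),
                     class = "force_trace")
  axes <- build_axes(lv_landmarks(c(0, 0, 80), c(0, 0, 0), c(20, 0, 5)))
  pr <- project_force(trace, axes)
  p2 <- write_force_trace(pr, phases, file.path(dir, "trace.csv"))
  tb <- read.csv(p2)
  expect_equal(nrow(tb), 40)
  expect_setequal(unique(tb$phase),
                  c("systole", "e_wave", "diastasis", "a_wave"))
  expect_equal(as.vector(table(tb$phase)[c("systole", "e_wave", "diastasis",
                                           "a_wave")]),
               c(15, 11, 4, 10))
  expect_equal(tb$F_long, pr$F_long, tolerance = 1e-9)
})
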