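test_that("axes construction handles the axis-aligned textbook case", {
  lm <- lv_landmarks(apex = c(0, 0, 80), mv_center = c(0, 0, 0),
                     aov_center = c(20, 0, 5))
  ax <- build_axes(lm)
  expect_equal(ax$e_long, c(0, 0, 1))
  expect_equal(abs(ax$e_sax1), c(1, 0, 0))
  expect_equal(abs(ax$e_sax2), c(0, 1, 0))
  # +e_sax1 points away from the aortic (anteroseptal) side
  expect_equal(ax$e_sax1, c(-1, 0, 0))
  # rv_direction override flips the sign when needed
  ax2 <- build_axes(lv_landmarks(c(0, 0, 80), c(0, 0, 0), c(20, 0, 5),
                                 rv_direction = c(-1, 0, 0)))
  expect_equal(ax2$e_sax1, c(1, 0, 0))
})

test_that("axes frames are right-handed orthonormal for random landmarks", {
  set.seed(12)
  for (i in 1:50) {
    lm <- lv_landmarks(apex = rnorm(3, sd = 40), mv_center = rnorm(3, sd = 40),
                       aov_center = rnorm(3, sd = 40))
    ax <- build_axes(lm)
    M <- cbind(ax$e_long, ax$e_sax1, ax$e_sax2)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
})

test_that("collinear landmarks are rejected", {
  expect_error(lv_landmarks(c(0, 0, 80), c(0, 0, 0), c(0, 0, 40)), "collinear")
  expect_error(lv_landmarks(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "apex")
})

test_that("force projection is norm-preserving and componentwise correct", {
  ax <- build_axes(lv_landmarks(c(0, 0, 0), c(0, 0, 80), c(20, 0, 75)))
  # e_long = (0,0,-1): an apex-directed force is purely long-axis
  trace <- structure(list(times = c(0, 500), F = rbind(c(0, 0, -1), c(0.3, 0.4, 0)),
                          terms = NULL, lv_volume = c(1e-4, 1e-4)),
                     class = "force_trace")
  pr <- project_force(trace, ax)
  expect_equal(pr$F_long[1], 1)             # toward apex
  expect_equal(pr$F_sax1[1], 0)
  expect_equal(pr$F_sax2[1], 0)
  expect_equal(pr$F_long[2], 0)             # in-plane force has no long comp.

  set.seed(13)
  Fs <- matrix(rnorm(30), 10, 3)
  tr2 <- structure(list(times = 1:10, F = Fs, terms = NULL,
                        lv_volume = rep(1e-4, 10)), class = "force_trace")
  pr2 <- project_force(tr2, ax)
  norm_in <- sqrt(rowSums(Fs^2))
  norm_out <- sqrt(pr2$F_long^2 + pr2$F_sax1^2 + pr2$F_sax2^2)
  expect_equal(norm_in, norm_out, tolerance = 1e-12)
})

test_that("speed traces interpolate trilinearly at the landmark points", {
  meta <- tiny_meta(n_frames = 3L, voxel = 2)
  f <- uniform_velocity(c(6, 6, 6), function(c, f) c(0.3, 0.4, 0)[c], meta)
  lm <- lv_landmarks(apex = c(5, 5, 9), mv_center = c(3.7, 4.2, 5.1),
                     aov_center = c(8, 5, 9))
  tr <- extract_speed_traces(f, lm)
  expect_equal(tr$mv_speed, rep(0.5, 3), tolerance = 1e-12)

  # a point on a voxel center reproduces that voxel's value
  f2 <- uniform_velocity(c(6, 6, 6), function(c, f) 0, meta)
  f2$values[3, 4, 2, 1, ] <- 0.7
  lm2 <- lv_landmarks(apex = c(5, 5, 9), mv_center = c(4, 6, 2),
                      aov_center = c(8, 5, 9))
  tr2 <- extract_speed_traces(f2, lm2)
  expect_equal(tr2$mv_speed, rep(0.7, 3))

  lm3 <- lv_landmarks(apex = c(5, 5, 9), mv_center = c(40, 5, 5),
                      aov_center = c(8, 5, 9))
  expect_error(extract_speed_traces(f, lm3), "outside")
})

test_that("phase detection segments a constructed biphasic cycle", {
  n <- 40L
  meta <- acquisition_meta(1, rep(3, 3), n, 1000)
  t_f <- meta$frame_times
  mv <- 0.8 * lvforce:::lobe(t_f, 400, 675) + 0.5 * lvforce:::lobe(t_f, 750, 1000)
  ao <- 0.9 * lvforce:::lobe(t_f, 25, 350)
  traces <- structure(list(mv_speed = mv, aov_speed = ao, time_ms = t_f),
                      class = "speed_traces")
  ph <- detect_phases(traces, meta)
  # MV lobes span frames 17-27 and 31-40: detected windows within one frame
  expect_lte(abs(min(ph$e_wave) - 17), 1)
  expect_lte(abs(max(ph$e_wave) - 27), 1)
  expect_lte(abs(min(ph$a_wave) - 31), 1)
  expect_equal(max(ph$a_wave), 40)
  # windows partition the cycle
  expect_identical(sort(c(ph$systole, ph$e_wave, ph$diastasis, ph$a_wave)),
                   1:40)
  # invariant to uniform rescaling of both traces
  tr2 <- traces; tr2$mv_speed <- 7.3 * mv; tr2$aov_speed <- 7.3 * ao
  ph2 <- detect_phases(tr2, meta)
  expect_identical(ph2[1:4], ph[1:4])
})

test_that("degenerate traces are flagged or rejected", {
  n <- 40L
  meta <- acquisition_meta(1, rep(3, 3), n, 1000)
  t_f <- meta$frame_times
  flat <- structure(list(mv_speed = rep(0, n), aov_speed = rep(0, n),
                         time_ms = t_f), class = "speed_traces")
  expect_error(detect_phases(flat, meta), "flat")

  # fused inflow: single MV peak -> empty A-wave with a warning
  fused <- structure(list(mv_speed = 0.8 * lvforce:::lobe(t_f, 400, 900),
                          aov_speed = 0.9 * lvforce:::lobe(t_f, 25, 350),
                          time_ms = t_f), class = "speed_traces")
  expect_warning(ph <- detect_phases(fused, meta), "single|fused")
  expect_length(ph$a_wave, 0)
  expect_gt(length(ph$e_wave), 0)
  expect_identical(sort(c(ph$systole, ph$e_wave, ph$diastasis, ph$a_wave)),
                   1:40)
})

test_that("phantom inflow peaks where the generator prescribed it", {
  ph <- cached_phantom()
  traces <- extract_speed_traces(ph$velocity_clean, ph$landmarks)
  e_win <- ph$truth$phases$e_wave
  # the E jet lobe peaks at the window midpoint
  expected_pk <- e_win[ceiling(length(e_win) / 2)]
  got_pk <- which.max(traces$mv_speed)
  expect_lte(abs(got_pk - expected_pk), 1)
  # detected windows match the prescribed ones within one frame
  det <- detect_phases(traces, ph$velocity_clean$meta)
  expect_lte(abs(min(det$e_wave) - min(e_win)), 1)
  expect_lte(abs(max(det$e_wave) - max(e_win)), 1)
  expect_lte(abs(min(det$a_wave) - min(ph$truth$phases$a_wave)), 1)
})
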