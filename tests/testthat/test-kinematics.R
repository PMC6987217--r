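# rigid-body fitting, Cardan decomposition, phase detection, filtering

test_that("fit_rigid_transform recovers exact rigid motions and validates geometry", {
  tmpl <- cube_template()
  fit0 <- fit_rigid_transform(tmpl, tmpl)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit0$residual_rms, 0, tolerance = 1e-12)

  R90 <- rot_about_z(90)
  obs <- tmpl %*% t(R90) + matrix(c(0.3, -0.1, 0.5), nrow(tmpl), 3,
                                  byrow = TRUE)
  fit <- fit_rigid_transform(tmpl, obs)
  expect_equal(rotation_angle_deg(fit$rotation), 90, tolerance = 1e-9)
  expect_equal(fit$translation, c(0.3, -0.1, 0.5), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)

  expect_error(fit_rigid_transform(tmpl[1:2, ], tmpl[1:2, ]), "3 points")
  expect_error(fit_rigid_transform(cbind(0:3, 0, 0), cbind(0:3, 0, 0)),
               "collinear")
  expect_error(fit_rigid_transform(tmpl, tmpl[1:4, ]), "mismatched")
})

test_that("fit residual matches a brute-force minimizer on a noisy instance", {
  tmpl <- cube_template()
  set.seed(314)
  R <- rotation_from_knee_angles(23, 7, -11)
  obs <- tmpl %*% t(R) + matrix(c(0.1, 0.2, 0.3), nrow(tmpl), 3,
                                byrow = TRUE) +
    matrix(rnorm(length(tmpl), 0, 0.004), nrow(tmpl), 3)
  fit <- fit_rigid_transform(tmpl, obs)
  # independent oracle: general-purpose optimiser over Cardan angles +
  # translation, started from several points
  obj <- function(par) {
    Rp <- rotation_from_knee_angles(par[1], par[2], par[3])
    fitted <- tmpl %*% t(Rp) + matrix(par[4:6], nrow(tmpl), 3, byrow = TRUE)
    sqrt(mean(rowSums((obs - fitted)^2)))
  }
  starts <- list(c(0, 0, 0, 0, 0, 0), c(20, 5, -10, 0.1, 0.2, 0.3),
                 c(45, -20, 30, 0, 0, 0))
  best <- min(vapply(starts, function(s) {
    stats::optim(s, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, 0))
  expect_equal(fit$residual_rms, best, tolerance = 1e-6)
})

test_that("fit is invariant to a common rigid motion of both point sets", {
  tmpl <- cube_template()
  set.seed(99)
  obs <- tmpl + matrix(rnorm(length(tmpl), 0, 0.01), nrow(tmpl), 3)
  base <- fit_rigid_transform(tmpl, obs)$residual_rms
  for (k in 1:5) {
    Q <- rotation_from_knee_angles(runif(1, -180, 180), runif(1, -60, 60),
                                   runif(1, -180, 180))
    v <- rnorm(3)
    shift <- function(m) m %*% t(Q) + matrix(v, nrow(m), 3, byrow = TRUE)
    moved <- fit_rigid_transform(shift(tmpl), shift(obs))$residual_rms
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("Cardan decomposition round-trips away from gimbal lock", {
  expect_equal(unname(knee_angles_from_rotation(diag(3))), c(0, 0, 0))
  expect_equal(
    unname(knee_angles_from_rotation(rotation_from_knee_angles(40, 0, 0))),
    c(40, 0, 0), tolerance = 1e-12)
  set.seed(123)
  for (i in 1:1000) {
    abc <- c(runif(1, -179, 179), runif(1, -79.9, 79.9), runif(1, -179, 179))
    back <- knee_angles_from_rotation(
      rotation_from_knee_angles(abc[1], abc[2], abc[3]))
    expect_equal(unname(back), abc, tolerance = 1e-9)
  }
  expect_warning(knee_angles_from_rotation(rotation_from_knee_angles(10, 90, 5)),
                 "gimbal")
  p1 <- fit_rigid_transform(cube_template(), cube_template())
  expect_equal(unname(knee_angles_from_poses(p1, p1)), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("detect_stance finds rectangular pulses and returns [] on silence", {
  expect_identical(detect_stance(rep(0, 500), 20, 1000), list())
  f <- rep(0, 1000)
  f[301:550] <- 1500                      # 0.25 s pulse at 1000 Hz
  st <- detect_stance(f, 20, 1000)
  expect_length(st, 1L)
  expect_lte(st[[1]]$start_index, 301L)
  expect_gte(st[[1]]$start_index, 300L)   # sub-sample refinement: +/-1 sample
  expect_gte(st[[1]]$end_index - 1L, 550L)
  expect_lte(st[[1]]$end_index - 1L, 551L)
  # intervals shorter than the minimum duration are discarded
  g <- rep(0, 1000); g[10:30] <- 1500     # 0.02 s blip
  expect_identical(detect_stance(g, 20, 1000, min_duration_s = 0.1), list())
})

test_that("stance detection recovers every generated stance in a stride train", {
  cfg <- cohort_config(seed = 17L)
  su <- make_subject()
  train <- unlist(lapply(1:8, function(k) {
    generate_running_trial(su, "neutral", k, cfg)$grf_vertical_N
  }))
  st <- detect_stance(train, 20, cfg$sampling_rate_mocap)
  expect_length(st, 8L)
})

test_that("eccentric phase runs from region start to the flexion peak", {
  ph <- detect_eccentric_phase(c(10, 20, 30, 25))
  expect_identical(c(ph$start_index, ph$end_index), c(1L, 4L))
  expect_error(detect_eccentric_phase(c(30, 25, 20)), "first sample")
  cfg <- cohort_config(seed = 3L)
  tr <- generate_squat_trial(make_subject(), 1L, cfg)
  ph2 <- detect_eccentric_phase(tr$flexion_deg)
  expect_identical(ph2$end_index - 1L, attr(tr, "truth")$peak_index)
})

test_that("critical-angle extraction interpolates, honours exact hits, and names failures", {
  tr <- trial(c(0, 0.01), c(30, 50), c(2, 6), c(1, 3))
  out <- angles_at_critical_flexion(tr, phase_interval(1, 3), 40)
  expect_equal(unname(out), c(4, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(out, "crossing_time_s"), 0.005, tolerance = 1e-12)

  tr2 <- trial(c(0, 0.01, 0.02), c(30, 40, 50), c(2, 9, 6), c(1, 7, 3))
  out2 <- angles_at_critical_flexion(tr2, phase_interval(1, 4), 40)
  expect_equal(unname(out2), c(9, 7), tolerance = 1e-12, ignore_attr = TRUE)

  tr3 <- trial(c(0, 0.01, 0.02), c(30, 35, 38), c(0, 0, 0), c(0, 0, 0),
               subject_id = "S99")
  expect_error(angles_at_critical_flexion(tr3, phase_interval(1, 4), 40),
               "no rising crossing.*S99")
})

test_that("critical-angle extraction is invariant to uniform time resampling", {
  cfg <- cohort_config(seed = 31L)
  su <- make_subject(noise_angle = 0)
  tr <- generate_squat_trial(su, 1L, cfg)
  ref <- critical_angles(tr, analysis_config(), filter = FALSE)
  for (fac in c(0.5, 2.5)) {
    t_new <- seq(tr$time[1], tr$time[length(tr$time)],
                 by = (tr$time[2] - tr$time[1]) / fac)
    rs <- trial(t_new,
                approx(tr$time, tr$flexion_deg, t_new)$y,
                approx(tr$time, tr$adduction_deg, t_new)$y,
                approx(tr$time, tr$int_rot_deg, t_new)$y,
                movement_kind = "squat", subject_id = tr$subject_id)
    out <- critical_angles(rs, analysis_config(), filter = FALSE)
    expect_equal(unname(out), unname(ref), tolerance = 0.05)
  }
})

test_that("lowpass preserves DC and passband, attenuates the stopband, validates cutoff", {
  x <- rep(3.7, 400)
  expect_equal(lowpass(x, 12, 200), x, tolerance = 1e-9)
  t <- seq(0, 2, by = 1 / 1000)
  s1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass(s1, 12, 1000)
  mid <- 300:1700
  expect_equal(max(abs(y1[mid])), max(abs(s1[mid])), tolerance = 0.01)
  s60 <- sin(2 * pi * 60 * t)
  y60 <- lowpass(s60, 12, 1000, order = 4L)
  expect_lt(max(abs(y60[mid])), 0.1)
  expect_error(lowpass(s1, 500, 1000), "Nyquist")
  expect_length(lowpass(rnorm(123), 12, 200), 123L)
})
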