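tt <- seq(0, 3, by = 0.01)

test_that("trunk flexion is the sum of pelvis tilt, lumbar and thoracic", {
  expect_equal(trunk_flexion(0, 0, 0), 0)
  expect_equal(trunk_flexion(20 * pi / 180, 15 * pi / 180, 5 * pi / 180), 40)
  expect_equal(trunk_flexion(10 * pi / 180, 0, 0), 10)
  set.seed(14)
  for (i in 1:20) {
    a <- runif(3, -1, 1)
    expect_equal(trunk_flexion(a[1], a[2], a[3]),
                 sum(a) * 180 / pi, tolerance = 1e-12)
  }
})

test_that("seat-off is the debounced chair unloading instant", {
  tr <- make_synth_traj(tt, list(chair_fy = ifelse(tt < 0.42, 500, 0),
                                 d_pelvis_tilt = 0.2))
  ev <- detect_events(tr)
  expect_equal(ev$seat_off, 0.42, tolerance = 0.011)
  # a trajectory that never unloads the chair has no seat-off
  ev2 <- detect_events(make_synth_traj(tt, list(chair_fy = 500)))
  expect_null(ev2$seat_off)
})

test_that("sub-debounce force flickers do not create events", {
  chair <- ifelse(tt < 1, 500, 0)
  chair[tt > 0.60 & tt < 0.63] <- 0      # 30 ms flicker
  tr <- make_synth_traj(tt, list(chair_fy = chair))
  expect_equal(detect_events(tr)$seat_off, 1.0, tolerance = 0.011)
  grf <- ifelse(tt < 1.5, 400, 0)
  grf[tt > 0.8 & tt < 0.83] <- 0
  tr2 <- make_synth_traj(tt, list(grf_l_fy = grf, chair_fy = 0))
  expect_equal(detect_events(tr2)$toe_offs_l, 1.5, tolerance = 0.011)
})

test_that("alternating ground reactions give ordered toe-offs and strikes", {
  grf_l <- 400 * as.numeric((tt %% 1) < 0.5)    # unloads at 0.5, 1.5, 2.5
  tr <- make_synth_traj(tt, list(grf_l_fy = grf_l, grf_r_fy = 400))
  ev <- detect_events(tr)
  expect_equal(ev$toe_offs_l, c(0.5, 1.5, 2.5), tolerance = 0.011)
  expect_equal(ev$heel_strikes_l, c(1.0, 2.0), tolerance = 0.011)
  expect_true(all(diff(ev$toe_offs) > 0))
})

test_that("metrics report hand-computable values on an analytic fixture", {
  tilt <- 0.1 * tt                      # rad, grows linearly
  tr <- make_synth_traj(tt, list(
    chair_fy = ifelse(tt < 1, 500, 0),
    grf_l_fy = ifelse(tt >= 1.4 & tt < 1.8, 0, 400),
    grf_r_fy = 400,
    pelvis_tilt = tilt, d_pelvis_tilt = 0.1,
    load_knee_l = 1471.5))
  ev <- detect_events(tr)
  met <- movement_metrics(tr, ev)
  expect_equal(met$trunk_flexion_at_seat_off, 0.1 * 1 * 180 / pi,
               tolerance = 0.02)
  expect_equal(met$time_to_first_heel_strike, 1.8 - ev$movement_onset,
               tolerance = 0.02)
  expect_equal(unname(met$peak_loads_bw[["knee_l"]]), 2, tolerance = 1e-9)
})

test_that("a constant-pose trajectory has max flexion at seat-off", {
  tr <- make_synth_traj(tt, list(chair_fy = ifelse(tt < 1, 500, 0),
                                 pelvis_tilt = 0.3, d_pelvis_tilt = 0.2))
  met <- movement_metrics(tr)
  expect_equal(met$max_trunk_flexion, met$trunk_flexion_at_seat_off,
               tolerance = 1e-9)
})

test_that("trajectory CSV round-trips and the .sto header is consistent", {
  p <- toy_scenes()$pendulum
  tr <- integrate_rollout(p$model, list(q = 0.4, qd = 0), NULL,
                          duration = 1, fall_floor = -Inf)
  dir <- tempfile(); dir.create(dir)
  files <- write_outputs(tr, dir, prefix = "pend", plots = FALSE)
  back <- read.csv(file.path(dir, "pend_trajectory.csv"))
  expect_equal(back$q1, tr$q1, tolerance = 1e-12)
  expect_identical(names(back), names(as.data.frame(tr)))
  sto <- readLines(file.path(dir, "pend.sto"))
  n_declared <- as.integer(sub("nRows=", "", sto[3]))
  header_at <- which(sto == "endheader")
  expect_equal(length(sto) - header_at - 1, n_declared)
  unlink(dir, recursive = TRUE)
})

test_that("full-body trajectory columns form a stable documented schema", {
  m <- build_default_model()
  tr <- integrate_rollout(m, seated_state(m), NULL, duration = 0.02)
  mus <- m$muscles$name
  want <- c("t", DOF_NAMES, paste0("d_", DOF_NAMES),
            paste0("u_", mus), paste0("a_", mus), paste0("F_", mus),
            paste0("lce_", mus), paste0("E_", mus),
            "grf_r_fx", "grf_r_fy", "grf_l_fx", "grf_l_fy",
            "chair_fx", "chair_fy",
            "load_hip_r", "load_knee_r", "load_ankle_r",
            "load_hip_l", "load_knee_l", "load_ankle_l",
            "tau_lumbar", "tau_thoracic", "lim_knee_r", "lim_knee_l",
            "head_ax", "head_ay", "mode", "state_leg_r", "state_leg_l")
  expect_identical(names(tr), want)
})
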