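test_that("pack/unpack round-trips losslessly and reports the layout count", {
  layout <- controller_layout()
  set.seed(21)
  x <- setNames(runif(nrow(layout), layout$lo, layout$hi), layout$name)
  x2 <- pack_params(unpack_params(x, layout), layout)
  expect_equal(x2, x)
  expect_identical(length(default_controller_params()), nrow(layout))
})

test_that("perturbing one vector entry changes exactly one packed scalar", {
  layout <- controller_layout()
  x <- default_controller_params()
  set.seed(8)
  for (i in sample(nrow(layout), 12)) {
    y <- x
    y[i] <- y[i] + 0.123
    x2 <- pack_params(unpack_params(y, layout), layout)
    expect_equal(sum(x2 != x), 1)
    expect_equal(unname(x2[i] - x[i]), 0.123)
  }
})

test_that("a wrong-length vector is rejected with a named error", {
  expect_error(unpack_params(c(a = 1, b = 2)), "length")
})

test_that("delayed signals interpolate and zero-pad before t = 0", {
  tt <- seq(0, 1, by = 0.01)
  r <- tt   # ramp r(t) = t
  expect_equal(delayed_signal(0.1, tt, r, 0.02), 0.08, tolerance = 1e-12)
  expect_equal(delayed_signal(0.5, tt, r, 0), 0.5)
  expect_equal(delayed_signal(0.3, tt, rep(7, length(tt)), 0.25), 7)
  expect_equal(delayed_signal(0.05, tt, r, 0.2), 0)   # before recording
})

test_that("the controller schedule is one-way with included boundaries", {
  sch <- list(t_state2 = 0.3, t_gait = 1.2)
  expect_identical(advance_state_machine(0, sch), "stand1")
  expect_identical(advance_state_machine(0.3, sch), "stand2")
  expect_identical(advance_state_machine(1.19, sch), "stand2")
  expect_identical(advance_state_machine(1.2, sch), "gait")
  expect_error(advance_state_machine(0, list(t_state2 = 1, t_gait = 0.5)),
               "t_gait")
  expect_error(reflex_controller(
    mk <- {x <- default_controller_params()
           x["sched_t_gait"] <- 0.2; x}), "t_gait")
})

test_that("the standing reflex law reproduces hand-computed excitations", {
  gains <- unpack_params(default_controller_params())$stand[[1]]
  gains$KC[] <- 0.3; gains$KL[] <- 0; gains$KFp[] <- 0; gains$KFm[] <- 0
  gains$KP[] <- 0; gains$KV[] <- 0
  sig <- data.frame(group = MUSCLE_GROUPS, lt = 1, ft = 0.2, ft_antag = 0.1)
  expect_equal(unname(stand_excitations(sig, gains)), rep(0.3, 10))
  # positive-part length feedback contributes nothing below the offset
  gains$KL[] <- 2; gains$LO[] <- 1.0
  sig$lt <- 0.9
  expect_equal(unname(stand_excitations(sig, gains)), rep(0.3, 10))
  # hand case: u = KC + KFp * F = 0.1 + 0.5 * 0.4 = 0.3
  gains$KC[] <- 0.1; gains$KL[] <- 0; gains$KFp[] <- 0.5
  sig$ft <- 0.4
  expect_equal(unname(stand_excitations(sig, gains)), rep(0.3, 10))
})

test_that("excitations stay in [0, 1] for any in-bounds gains", {
  layout <- controller_layout()
  set.seed(33)
  for (rep in 1:20) {
    x <- setNames(runif(nrow(layout), layout$lo, layout$hi), layout$name)
    gains <- unpack_params(x)$stand[[sample(2, 1)]]
    sig <- data.frame(group = MUSCLE_GROUPS,
                      lt = runif(10, 0.3, 1.8), ft = runif(10),
                      ft_antag = runif(10))
    u <- stand_excitations(sig, gains, theta = runif(1, -1, 1),
                           thetad = runif(1, -3, 3))
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("gait excitations mirror under mirrored leg states", {
  gait <- unpack_params(default_controller_params())$gait
  sig <- data.frame(group = MUSCLE_GROUPS, lt = runif(10, 0.8, 1.2),
                    ft = runif(10), ft_sol = 0.5)
  for (st in c("early_stance", "late_stance", "liftoff", "swing",
               "landing")) {
    uL <- gait_excitations(sig, gait, st, theta = 0.1, thetad = -0.2)
    uR <- gait_excitations(sig, gait, st, theta = 0.1, thetad = -0.2)
    expect_identical(uL, uR)
  }
})

test_that("gait phase gating switches the active reflex pathways", {
  gait <- unpack_params(default_controller_params())$gait
  sig <- data.frame(group = MUSCLE_GROUPS, lt = 1, ft = 0.5, ft_sol = 0.5)
  u_st <- gait_excitations(sig, gait, "early_stance")
  u_sw <- gait_excitations(sig, gait, "swing")
  # stance: soleus force feedback on; swing: off
  expect_gt(u_st[["sol"]], 0.4)
  expect_lt(u_sw[["sol"]], 0.05)
  # swing: hip flexor drive on
  expect_gt(u_sw[["ilpso"]], u_st[["ilpso"]])
})

test_that("controller parameter files round-trip", {
  x <- default_controller_params()
  f <- tempfile(fileext = ".txt")
  write_params(x, f)
  y <- read_params(f)
  expect_equal(y, x)
  unlink(f)
})
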