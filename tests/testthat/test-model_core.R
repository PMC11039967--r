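test_that("default model satisfies its structural invariants", {
  m <- build_default_model()
  expect_equal(m$total_mass, 75)
  expect_equal(m$height, 1.80)
  expect_equal(nrow(m$dofs), 11)
  expect_equal(nrow(m$muscles), 20)
  expect_equal(sum(vapply(m$segments, `[[`, "", "jkind") == "planar_free"), 1)
})

test_that("invalid configurations are rejected with validation errors", {
  cfg <- default_model_config()
  cfg$segments$masses[["thigh"]] <- 0
  expect_error(build_default_model(cfg), "positive")
  m <- build_default_model()
  m$segments[[3]] <- NULL   # drop a joint: DOF count no longer matches
  expect_error(validate_model(m), "DOF count")
})

test_that("an unactuated free body is in free fall", {
  d <- toy_scenes()$drop_test
  qdd <- forward_dynamics(d$model, q = c(0, 10, 0), qd = c(0, 0, 0))
  expect_equal(qdd, c(0, -9.81, 0), tolerance = 1e-12)
})

test_that("pendulum dynamics match the closed form to 1e-8 relative", {
  p <- toy_scenes()$pendulum
  for (q in c(-2.1, -0.7, 0.3, 1.4)) {
    got <- forward_dynamics(p$model, q, 0)
    expect_equal(got, p$oracle$qdd(q), tolerance = 1e-8)
  }
})

test_that("double-pendulum dynamics match the independent Lagrangian oracle", {
  sc <- toy_scenes()$double_pendulum
  set.seed(42)
  for (i in 1:10) {
    q <- runif(2, -1.5, 1.5)
    qd <- runif(2, -3, 3)
    got <- forward_dynamics(sc$model, q, qd)
    want <- double_pendulum_oracle_qdd(sc, q, qd)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("random applied torques on the 2-link toy match the oracle", {
  sc <- toy_scenes()$double_pendulum
  set.seed(7)
  q <- c(0.5, -0.8); qd <- c(1.2, -0.4); tau <- c(2.3, -1.1)
  mm <- mass_matrix(sc$model, q, qd)
  got <- forward_dynamics(sc$model, q, qd, applied = tau)
  base <- double_pendulum_oracle_qdd(sc, q, qd)
  want <- base + solve(mm$M, tau)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("pendulum mechanical energy is conserved to 0.1% over 5 s", {
  p <- toy_scenes()$pendulum
  tr <- integrate_rollout(p$model, list(q = 1.0, qd = 0), NULL,
                          duration = 5, fall_floor = -Inf)
  E <- vapply(seq_len(nrow(tr)), function(i)
    mechanical_energy(p$model, tr$q1[i], tr$d_q1[i]), 0)
  expect_lt((max(E) - min(E)) / abs(E[1]), 0.001)
})

test_that("pendulum period matches 2*pi*sqrt(Io/mgd) at small amplitude", {
  p <- toy_scenes()$pendulum
  tr <- integrate_rollout(p$model, list(q = 0.05, qd = 0), NULL,
                          duration = 6, out_dt = 0.001, fall_floor = -Inf)
  s <- sign(tr$q1)
  crossings <- tr$t[which(diff(s) != 0)]
  period <- 2 * mean(diff(crossings))
  expect_equal(period, p$oracle$period, tolerance = 0.005)
})

test_that("a zero-duration call returns only the initial state", {
  p <- toy_scenes()$pendulum
  tr <- integrate_rollout(p$model, list(q = 0.3, qd = 0), NULL,
                          duration = 0, fall_floor = -Inf)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$q1, 0.3)
})

test_that("the drop test settles at the sphere's weight within 1%", {
  d <- toy_scenes()$drop_test
  tr <- integrate_rollout(d$model, list(q = d$q0, qd = c(0, 0, 0)), NULL,
                          duration = 2, fall_floor = -Inf)
  expect_equal(tail(tr$grf_r_fy, 1), d$oracle$weight, tolerance = 0.01)
})

test_that("failed rollouts are flagged, not raised", {
  m <- build_default_model()
  st <- seated_state(m)
  st$q["pelvis_x"] <- st$q["pelvis_x"] + 2   # seated pose with no chair below
  st$q["pelvis_y"] <- 1.5
  tr <- integrate_rollout(m, st, NULL, duration = 2)
  expect_true(attr(tr, "status") %in% c("fell", "blowup"))
})

test_that("moment arms equal length-gradient finite differences", {
  m <- build_default_model()
  set.seed(3)
  h <- 1e-6
  for (rep in 1:5) {
    q <- runif(11, -0.5, 0.5)
    mg <- muscle_geometry(m, q)
    for (d in c(4, 5, 6, 9)) {      # hip_r, knee_r, ankle_r, lumbar
      qp <- q; qp[d] <- q[d] + h
      qm <- q; qm[d] <- q[d] - h
      fd <- (muscle_geometry(m, qp)$length -
               muscle_geometry(m, qm)$length) / (2 * h)
      expect_equal(unname(-fd), unname(mg$arms[, d]), tolerance = 1e-6)
    }
  }
})

test_that("a constant-arm muscle shortens by arm times joint rotation", {
  sc <- toy_scenes()$lever_muscle
  L0 <- muscle_geometry(sc$model, 0)$length
  dq <- 0.3
  L1 <- muscle_geometry(sc$model, dq)$length
  expect_equal(unname(L1 - L0), -sc$oracle$arm * dq, tolerance = 1e-12)
})

test_that("identical inputs give bit-identical trajectories", {
  m <- build_default_model()
  st <- seated_state(m)
  ctrl <- reflex_controller()
  t1 <- integrate_rollout(m, st, ctrl, duration = 0.5)
  t2 <- integrate_rollout(m, st, ctrl, duration = 0.5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})
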