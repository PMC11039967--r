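# Objective terms on constructed rectangle fixtures. Trajectories are built
# with make_synth_traj(); a heel strike is induced by a GRF that is zero
# early and positive afterwards.

tt <- seq(0, 3, by = 0.01)

walk_traj <- function(speed) {
  # stepping-leg toe-off at 1.0 s, heel strike at 1.5 s, then steady walking
  grf_l <- ifelse(tt < 1 | tt >= 1.5, 400, 0)
  make_synth_traj(tt, list(
    chair_fy = ifelse(tt < 0.5, 500, 0),
    grf_r_fy = 400,
    grf_l_fy = grf_l,
    pelvis_x = pmax(0, tt - 1.5) * speed,
    pelvis_y = 0.95,
    d_pelvis_tilt = 0.2))
}

test_that("velocity term is zero at or above threshold, squared below", {
  expect_equal(velocity_term(walk_traj(0.9), 0.8), 0)
  expect_equal(velocity_term(walk_traj(0.8), 0.8), 0, tolerance = 1e-6)
  expect_equal(velocity_term(walk_traj(0.6), 0.8), 0.04, tolerance = 1e-3)
})

test_that("range penalty integrates excursion beyond a closed interval", {
  dt <- 0.01
  inside <- rep(0.5, 200)
  expect_equal(range_penalty(inside, 0, 1, dt), 0)
  # constant 5 deg beyond hi for 2 s -> 10 deg s
  over <- rep(15, 200)      # hi = 10 deg
  expect_equal(range_penalty(over, -10, 10, dt), 10, tolerance = 1e-9)
  # boundary-touching series incurs nothing
  expect_equal(range_penalty(c(rep(10, 100), rep(-10, 100)), -10, 10, dt), 0)
})

test_that("knee limit term integrates the recorded limit force", {
  tr <- make_synth_traj(tt, list(lim_knee_r = ifelse(tt < 1, 500 * 0.1, 0)))
  expect_equal(knee_limit_term(tr), 500 * 0.1 * 1, tolerance = 0.01)
  tr2 <- make_synth_traj(tt, list(lim_knee_r = ifelse(tt < 1, 50, 0),
                                  lim_knee_l = ifelse(tt < 0.5, 20, 0)))
  expect_equal(knee_limit_term(tr2), 50 + 10, tolerance = 0.01)
})

test_that("head acceleration term integrates excess above 1 m/s^2", {
  tr <- make_synth_traj(tt, list(head_ax = ifelse(tt < 0.5, 3, 0)))
  expect_equal(head_acc_term(tr), 1.0, tolerance = 0.02)
  expect_equal(head_acc_term(make_synth_traj(tt)), 0)
})

test_that("cubed-activation and trunk-torque efforts integrate as stated", {
  tr <- make_synth_traj(tt, list(a_m1 = ifelse(tt < 2, 0.5, 0)))
  eff <- effort_terms(tr)
  expect_equal(eff$J_act, 0.5^3 * 2, tolerance = 1e-2)
  expect_equal(eff$J_T, 0)
  tr2 <- make_synth_traj(tt, list(tau_lumbar = 10, tau_thoracic = 5))
  expect_equal(effort_terms(tr2)$J_T, (100 + 25) * 3, tolerance = 1)
})

test_that("metabolic effort is normalized per phase", {
  # constant 150 W total rate; no gait: plain J per kg
  tr <- make_synth_traj(tt, list(E_m1 = 150))
  expect_equal(effort_terms(tr)$J_mb, 150 * 3 / 75, tolerance = 0.01)
  # with a gait phase from t = 1.5 and 1 m travelled, the gait part is a
  # cost of transport
  tr2 <- walk_traj(2 / 3)
  tr2$E_m1 <- 150
  d <- tr2$pelvis_x[nrow(tr2)] - tr2$pelvis_x[tr2$t == 1.5]
  want <- 150 * 1.5 / 75 + 150 * 1.5 / (75 * d)
  expect_equal(effort_terms(tr2)$J_mb, want, tolerance = 0.02)
})

test_that("joint loads convert to body weights", {
  tr <- make_synth_traj(tt, list(load_knee_l = 1471.5))
  expect_equal(joint_load(tr, "knee", "l"), rep(2, length(tt)),
               tolerance = 1e-9)
})

test_that("pain term matches the rectangle integral and the BW definition", {
  bw <- 735.75
  load3 <- rep(3 * bw, 101)   # 3 BW for 1 s at 100 Hz
  expect_equal(pain_term(load3, 4, bw, 0.01), 0)
  expect_equal(pain_term(load3, 2, bw, 0.01), 735.75 * 1.01,
               tolerance = 1e-9)
})

test_that("pain term is non-increasing in the threshold", {
  bw <- 735.75
  set.seed(2)
  load <- abs(rnorm(300, 2.5, 1)) * bw
  vals <- vapply(c(2, 2.5, 3, 3.5, 4), function(th)
    pain_term(load, th, bw, 0.01), 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("joint loads in BW are invariant to the force unit", {
  tr_n <- make_synth_traj(tt, list(load_knee_l = 1471.5))
  tr_kn <- make_synth_traj(tt, list(load_knee_l = 1.4715),
                           model_mass = 0.075)  # forces expressed in kN
  expect_equal(joint_load(tr_n, "knee", "l"), joint_load(tr_kn, "knee", "l"),
               tolerance = 1e-9)
})

test_that("the total reduces to the weighted energy sum when penalties are
           zero, and adds up term-wise", {
  tr <- walk_traj(0.9)
  tr$E_m1 <- 100
  tr$a_m1 <- 0.4
  tr$tau_lumbar <- 8
  tr$pelvis_y <- 0.95
  tr$pelvis_x <- tr$pelvis_x + 2    # travel target met
  cfg <- objective_config()
  rep <- evaluate_objective(tr, cfg)
  expect_equal(rep$J_velocity, 0)
  expect_equal(sum(rep$J_range), 0)
  expect_equal(rep$J_knee_limit, 0)
  expect_equal(rep$J_head_acc, 0)
  expect_equal(rep$J_shape, 0)
  expect_equal(rep$J_total,
               0.01 * rep$J_mb + 0.1 * rep$J_act + 3e-4 * rep$J_T,
               tolerance = 1e-9)
  # additivity with a pain cost switched on
  cfg2 <- objective_config(pain_threshold_bw = 2)
  tr$load_knee_l <- 3 * 735.75
  rep2 <- evaluate_objective(tr, cfg2)
  expect_equal(rep2$J_total,
               rep2$J_velocity + sum(rep2$J_range) + rep2$J_knee_limit +
                 rep2$J_head_acc + 0.01 * rep2$J_mb + 0.1 * rep2$J_act +
                 3e-4 * rep2$J_T + rep2$J_pain + rep2$J_shape,
               tolerance = 1e-9)
  expect_gt(rep2$J_pain, 0)
})

test_that("failed rollouts cost more than any completed movement", {
  tr <- make_synth_traj(tt, status = "fell")
  rep <- evaluate_objective(tr)
  expect_true(rep$failed)
  expect_gte(rep$J_total, 1e4)
})
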