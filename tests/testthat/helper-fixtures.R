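# Shared helpers: synthetic trajectories with the engine's column schema and
# an independent double-pendulum oracle derived from textbook equations.

# Build a minimal synthetic stw_trajectory. Unspecified columns are zero.
make_synth_traj <- function(t, cols = list(), model_mass = 75,
                            gravity = 9.81, status = "ok") {
  n <- length(t)
  base <- list(t = t)
  needed <- c("pelvis_x", "pelvis_y", "pelvis_tilt", "lumbar", "thoracic",
              "ankle_r", "ankle_l",
              "d_pelvis_tilt", "d_hip_r", "d_hip_l", "d_lumbar",
              "chair_fy", "grf_r_fy", "grf_l_fy",
              "lim_knee_r", "lim_knee_l", "head_ax", "head_ay",
              "tau_lumbar", "tau_thoracic",
              "load_knee_r", "load_knee_l", "load_hip_r", "load_hip_l",
              "load_ankle_r", "load_ankle_l")
  for (nm in needed) base[[nm]] <- rep(0, n)
  base$a_m1 <- rep(0, n)   # one synthetic muscle
  base$E_m1 <- rep(0, n)
  for (nm in names(cols)) base[[nm]] <- rep_len(cols[[nm]], n)
  traj <- as.data.frame(base)
  attr(traj, "status") <- status
  attr(traj, "model_mass") <- model_mass
  attr(traj, "gravity") <- gravity
  class(traj) <- c("stw_trajectory", "data.frame")
  traj
}

# Independent double-pendulum oracle: textbook equations of motion for two
# distributed-mass rods, absolute angles theta measured counterclockwise
# from the downward vertical. The package stores clockwise-from-vertical
# joint angles, so theta1 = -q1 and theta2 = -(q1 + q2).
double_pendulum_oracle_qdd <- function(scene, q, qd) {
  o <- scene$oracle
  m1 <- o$m1; L1 <- o$L1; m2 <- o$m2; L2 <- o$L2
  d1 <- L1 / 2; d2 <- L2 / 2
  I1 <- m1 * L1^2 / 12; I2 <- m2 * L2^2 / 12
  g <- 9.81
  th1 <- -q[1]; th2 <- -(q[1] + q[2])
  w1 <- -qd[1]; w2 <- -(qd[1] + qd[2])
  A <- matrix(c(I1 + m1 * d1^2 + m2 * L1^2,
                m2 * L1 * d2 * cos(th1 - th2),
                m2 * L1 * d2 * cos(th1 - th2),
                I2 + m2 * d2^2), 2, 2)
  b <- c(-m2 * L1 * d2 * sin(th1 - th2) * w2^2 -
           (m1 * d1 + m2 * L1) * g * sin(th1),
         m2 * L1 * d2 * sin(th1 - th2) * w1^2 - m2 * d2 * g * sin(th2))
  thdd <- solve(A, b)
  q1dd <- -thdd[1]
  q2dd <- -thdd[2] - q1dd
  c(q1dd, q2dd)
}
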