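## Composite movement objective: gait velocity, joint-range penalties, knee
## limit force, head acceleration, metabolic energy / cubed activation /
## trunk torque effort terms, and the optional knee-load pain-avoidance
## cost. Hard measures are summed penalties that reach 0 on a satisfying
## movement, so the weighted energy estimate
## 0.01 Jmb + 0.1 Jact + 0.0003 JT (+ pain) is the sole non-zero term of a
## feasible solution.

#' Objective configuration
#'
#' Thresholds, ranges and weights of the composite objective. Joint ranges
#' are expressed in this package's forward-flexion-positive convention
#' (lumbar 0..50 deg flexion, thorax +/-15 deg, pelvis -30..50 deg, ankle
#' +/-60 deg); the knee limit spring (500 N m/rad) engages beyond 120 deg
#' flexion or 10 deg (hyper)extension and acts in the dynamics, so its
#' force series is read from the trajectory.
#'
#' @param v_min minimum average gait velocity, m/s.
#' @param w_mb,w_act,w_T weights of the metabolic, cubed-activation and
#'   trunk-torque terms.
#' @param pain_threshold_bw stepping-knee peak-load threshold in multiples
#'   of body weight, or `NULL` for no pain cost.
#' @param pain_leg which knee the pain cost watches.
#' @param w_vel,w_range,w_klim,w_head,w_pain penalty scales of the hard
#'   measures (forms are package choices; thresholds are fixed).
#' @param x_target forward pelvis travel used by the failed-rollout shaping
#'   term, m.
#' @return list of class `stw_objective_config`.
#' @export
objective_config <- function(v_min = 0.8, w_mb = 0.01, w_act = 0.1,
                             w_T = 3e-4, pain_threshold_bw = NULL,
                             pain_leg = "l", w_vel = 100, w_range = 100,
                             w_klim = 0.1, w_head = 1, w_pain = 0.02,
                             x_target = 1.5) {
  stopifnot(v_min > 0, w_mb >= 0, w_act >= 0, w_T >= 0)
  structure(list(
    v_min = v_min, w_mb = w_mb, w_act = w_act, w_T = w_T,
    pain_threshold_bw = pain_threshold_bw, pain_leg = pain_leg,
    w_vel = w_vel, w_range = w_range, w_klim = w_klim, w_head = w_head,
    w_pain = w_pain, x_target = x_target,
    w_standup = 50, w_travel = 20, standing_height = 0.92,
    w_noseatoff = 300,
    range_limits = list(
      lumbar = c(0, 50) * pi / 180,
      thoracic = c(-15, 15) * pi / 180,
      pelvis_tilt = c(-30, 50) * pi / 180,
      ankle = c(-60, 60) * pi / 180),
    failure_cost = 1e4), class = "stw_objective_config")
}

traj_dt <- function(traj) if (nrow(traj) > 1) traj$t[2] - traj$t[1] else 0

#' Gait-velocity shortfall term
#'
#' Zero when the average forward velocity over the gait phase (first heel
#' strike to end of rollout) meets `v_min`; squared shortfall otherwise.
#' Without any heel strike the term falls back to the average pelvis
#' velocity over the final second plus a fixed offset, its configured
#' maximum-penalty regime, which keeps the cost landscape informative for
#' rollouts that never reach gait.
#'
#' @param traj an `stw_trajectory`.
#' @param v_min threshold velocity, m/s.
#' @param events precomputed [detect_events()] result (optional).
#' @param w_vel penalty scale.
#' @return non-negative cost.
#' @export
velocity_term <- function(traj, v_min = 0.8, events = NULL, w_vel = 1) {
  if (is.null(events)) events <- detect_events(traj)
  hs <- events$gait_start
  if (!is.null(hs)) {
    t0 <- hs[1]
    sel <- traj$t >= t0
    if (sum(sel) >= 2) {
      v <- (traj$pelvis_x[nrow(traj)] - traj$pelvis_x[which(sel)[1]]) /
        (traj$t[nrow(traj)] - t0 + 1e-9)
      return(w_vel * max(0, v_min - v)^2)
    }
  }
  # no gait phase: maximum-penalty regime with velocity shaping
  sel <- traj$t >= max(0, traj$t[nrow(traj)] - 1)
  v <- if (sum(sel) >= 2)
    (traj$pelvis_x[nrow(traj)] - traj$pelvis_x[which(sel)[1]]) /
      (traj$t[nrow(traj)] - traj$t[which(sel)[1]] + 1e-9) else 0
  w_vel * (max(0, v_min - min(v, v_min))^2 + 0.5 * v_min^2)
}

#' Range-excursion penalty
#'
#' Time integral of the excursion of a series beyond a closed interval;
#' zero iff the series never leaves it.
#'
#' @param series sampled values.
#' @param lo,hi interval bounds (same units as the series).
#' @param dt sampling interval.
#' @return integral of the excursion (unit x s).
#' @export
range_penalty <- function(series, lo, hi, dt) {
  stopifnot(lo < hi)
  sum(pmax(0, series - hi) + pmax(0, lo - series)) * dt
}

#' Knee-limit force term
#'
#' Time integral of the magnitude of the passive knee limit-spring force
#' recorded during simulation; zero iff both knees stay within the
#' 120 deg flexion / 10 deg extension range.
#'
#' @param traj an `stw_trajectory`.
#' @return integral in N m s.
#' @export
knee_limit_term <- function(traj) {
  dt <- traj_dt(traj)
  sum(abs(traj$lim_knee_r) + abs(traj$lim_knee_l)) * dt
}

#' Head-acceleration term
#'
#' Time integral of head-acceleration magnitude in excess of a comfort
#' threshold (default 1 m/s^2).
#'
#' @param traj an `stw_trajectory`.
#' @param threshold m/s^2.
#' @return integral in m/s.
#' @export
head_acc_term <- function(traj, threshold = 1) {
  a <- sqrt(traj$head_ax^2 + traj$head_ay^2)
  sum(pmax(0, a - threshold)) * traj_dt(traj)
}

#' Effort terms: metabolic, cubed activation, trunk torque
#'
#' `J_mb` integrates the summed per-muscle metabolic rate, normalized by
#' body mass over the stand-up phase (start to first heel strike) and by
#' mass x distance (cost of transport) over the gait phase. `J_act`
#' integrates summed cubed activations; `J_T` integrates squared lumbar and
#' thoracic actuator torques.
#'
#' @param traj an `stw_trajectory`.
#' @param events precomputed events (optional).
#' @return list with `J_mb` (J/kg + J/(kg m)), `J_act` (s), `J_T`
#'   ((N m)^2 s).
#' @export
effort_terms <- function(traj, events = NULL) {
  if (is.null(events)) events <- detect_events(traj)
  dt <- traj_dt(traj)
  mass <- attr(traj, "model_mass")
  Ecols <- grep("^E_", names(traj), value = TRUE)
  acols <- grep("^a_", names(traj), value = TRUE)
  Edot <- rowSums(traj[Ecols])
  hs1 <- if (!is.null(events$gait_start)) events$gait_start else Inf
  standup <- traj$t < hs1
  J_mb <- sum(Edot[standup]) * dt / mass
  if (any(!standup)) {
    d <- max(0.1, traj$pelvis_x[nrow(traj)] - traj$pelvis_x[which(!standup)[1]])
    J_mb <- J_mb + sum(Edot[!standup]) * dt / (mass * d)
  }
  J_act <- sum(rowSums(traj[acols]^3)) * dt
  J_T <- sum(traj$tau_lumbar^2 + traj$tau_thoracic^2) * dt
  list(J_mb = J_mb, J_act = J_act, J_T = J_T)
}

#' Joint load series in body weights
#'
#' Resultant joint reaction force (rigid-body constraint force plus the
#' compressive contribution of muscles spanning the joint) divided by body
#' weight.
#'
#' @param traj an `stw_trajectory`.
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`.
#' @param side `"r"` or `"l"` (the left leg is the stepping leg).
#' @return numeric vector, one value per sample, in BW.
#' @export
joint_load <- function(traj, joint = c("hip", "knee", "ankle"),
                       side = c("r", "l")) {
  joint <- match.arg(joint); side <- match.arg(side)
  bw <- attr(traj, "model_mass") * attr(traj, "gravity")
  traj[[paste0("load_", joint, "_", side)]] / bw
}

#' Pain-avoidance cost on the stepping-knee load
#'
#' Integrates the knee load of the configured leg above `threshold x BW`
#' over the whole movement; zero iff the peak load stays below the
#' threshold. Returned in N s (unweighted).
#'
#' @param load_series knee load in N.
#' @param threshold_bw threshold in multiples of body weight.
#' @param bw body weight in N.
#' @param dt sampling interval, s.
#' @return integral in N s.
#' @export
pain_term <- function(load_series, threshold_bw, bw, dt) {
  stopifnot(threshold_bw > 0)
  sum(pmax(0, load_series - threshold_bw * bw)) * dt
}

#' Evaluate the composite objective on a trajectory
#'
#' Returns all per-term values and the weighted total. Failed rollouts
#' (fall or integration blow-up) receive the failure cost plus a shaping
#' term proportional to the forward distance still missing, keeping them
#' strictly worse than any completed rollout.
#'
#' @param traj an `stw_trajectory`.
#' @param config an [objective_config()].
#' @return list of class `stw_objective_report`.
#' @export
evaluate_objective <- function(traj, config = objective_config()) {
  status <- attr(traj, "status")
  bw <- attr(traj, "model_mass") * attr(traj, "gravity")
  if (!identical(status, "ok")) {
    prog <- max(0, config$x_target - max(traj$pelvis_x))
    total <- config$failure_cost + 100 * prog
    return(structure(list(failed = TRUE, status = status, J_total = total),
                     class = "stw_objective_report"))
  }
  events <- detect_events(traj)
  dt <- traj_dt(traj)
  J_vel <- velocity_term(traj, config$v_min, events, config$w_vel)
  rl <- config$range_limits
  J_range <- c(
    lumbar = range_penalty(traj$lumbar, rl$lumbar[1], rl$lumbar[2], dt),
    thoracic = range_penalty(traj$thoracic, rl$thoracic[1],
                             rl$thoracic[2], dt),
    pelvis = range_penalty(traj$pelvis_tilt, rl$pelvis_tilt[1],
                           rl$pelvis_tilt[2], dt),
    ankle_r = range_penalty(traj$ankle_r, rl$ankle[1], rl$ankle[2], dt),
    ankle_l = range_penalty(traj$ankle_l, rl$ankle[1], rl$ankle[2], dt)
  ) * config$w_range
  J_klim <- config$w_klim * knee_limit_term(traj)
  J_head <- config$w_head * head_acc_term(traj)
  eff <- effort_terms(traj, events)
  J_pain <- 0
  if (!is.null(config$pain_threshold_bw)) {
    load <- traj[[paste0("load_knee_", config$pain_leg)]]
    J_pain <- config$w_pain *
      pain_term(load, config$pain_threshold_bw, bw, dt)
  }
  # progress shaping for incomplete movements: ending below standing pelvis
  # height or short of the travel target is penalized; both terms vanish on
  # a completed sit-to-walk, so they only shape the approach to a solution
  tail_sel <- traj$t >= traj$t[nrow(traj)] - 0.5
  J_shape <- config$w_standup *
    max(0, config$standing_height - mean(traj$pelvis_y[tail_sel])) +
    config$w_travel * max(0, config$x_target - traj$pelvis_x[nrow(traj)])
  # the task is to rise unaided: a movement that starts seated and never
  # reaches seat-off pays the maximum-penalty regime of the shaping term
  if (traj$chair_fy[1] > 5 && is.null(events$seat_off))
    J_shape <- J_shape + config$w_noseatoff
  J_total <- J_vel + sum(J_range) + J_klim + J_head +
    config$w_mb * eff$J_mb + config$w_act * eff$J_act +
    config$w_T * eff$J_T + J_pain + J_shape
  structure(list(
    failed = FALSE, status = status,
    J_velocity = J_vel, J_range = J_range, J_knee_limit = J_klim,
    J_head_acc = J_head, J_mb = eff$J_mb, J_act = eff$J_act,
    J_T = eff$J_T, J_pain = J_pain, J_shape = J_shape, J_total = J_total,
    feasible = (J_vel + sum(J_range) + J_klim + J_head) < 1e-6,
    events = events), class = "stw_objective_report")
}

#' @export
print.stw_objective_report <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("<objective> FAILED rollout (%s), J_total = %.1f\n",
                x$status, x$J_total))
  } else {
    cat(sprintf(paste0("<objective> J_total = %.4f (vel %.3f, range %.3f, ",
                       "knee %.3f, head %.3f, mb %.3f, act %.3f, T %.3f, ",
                       "pain %.3f)\n"),
                x$J_total, x$J_velocity, sum(x$J_range), x$J_knee_limit,
                x$J_head_acc, x$J_mb, x$J_act, x$J_T, x$J_pain))
  }
  invisible(x)
}
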