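## Forward dynamics and rollout integration (R surface over the compiled core)

#' Forward dynamics of the articulated model
#'
#' Solves the planar equations of motion `M(q) qdd = applied - bias(q, qd)`
#' for the generalized accelerations; gravity is part of the bias so a free
#' unactuated body accelerates at -g.
#'
#' @param model an `stw_model` (full body or toy scene).
#' @param q,qd generalized coordinates and velocities.
#' @param applied generalized force vector (N or N m per coordinate);
#'   defaults to zero.
#' @return numeric vector of accelerations, one per coordinate.
#' @export
forward_dynamics <- function(model, q, qd, applied = numeric(model_nq(model))) {
  nq <- model_nq(model)
  stopifnot(length(q) == nq, length(qd) == nq, length(applied) == nq)
  as.numeric(.forward_dynamics_cpp(compile_model(model), as.numeric(q),
                                   as.numeric(qd), as.numeric(applied)))
}

#' Mass matrix, bias forces and potential energy
#'
#' @inheritParams forward_dynamics
#' @return list with the joint-space mass matrix `M`, velocity-product bias
#'   `bias`, generalized gravity force `Qg`, potential energy `pe` and the
#'   2 x nseg world COM positions `com`.
#' @export
mass_matrix <- function(model, q, qd = numeric(model_nq(model))) {
  .mass_matrix_cpp(compile_model(model), as.numeric(q), as.numeric(qd))
}

#' Total mechanical energy of a state
#'
#' Kinetic plus gravitational potential energy; used by the
#' energy-conservation checks on unactuated, contact-free scenes.
#'
#' @inheritParams forward_dynamics
#' @return energy in J.
#' @export
mechanical_energy <- function(model, q, qd) {
  mm <- mass_matrix(model, q, qd)
  0.5 * as.numeric(t(qd) %*% mm$M %*% qd) + mm$pe
}

#' Muscle-tendon lengths and moment arms
#'
#' Lengths follow the constant-moment-arm path model
#' `L(q) = L0 - sum_j r_j q_j`; the moment arm about a coordinate equals
#' `-dL/dq_j`, so a positive arm drives the coordinate positive.
#'
#' @param model an `stw_model` with muscles.
#' @param q generalized coordinates.
#' @return list with `length` (m, per muscle) and the muscle x coordinate
#'   moment-arm matrix `arms` (m).
#' @export
muscle_geometry <- function(model, q) {
  out <- .muscle_geometry_cpp(compile_model(model), as.numeric(q))
  out$length <- as.numeric(out$length)
  names(out$length) <- model$muscles$name
  dimnames(out$arms) <- list(model$muscles$name, model$dofs$name)
  out
}

#' Integrate a rollout
#'
#' Fixed-step semi-implicit (symplectic) Euler integration of the full
#' neuromusculoskeletal plant: muscle activation dynamics, Hill-type forces,
#' Hunt-Crossley contact and joint limit forces are evaluated every internal
#' step; the trajectory is sampled at `out_dt`. A rollout terminates early
#' and is flagged (not an error) when the pelvis drops below `fall_floor`
#' or any generalized velocity exceeds `qd_cap`.
#'
#' @param model an `stw_model`.
#' @param state initial state list with `q`, `qd` and optionally `act`
#'   (e.g. from [seated_state()]).
#' @param controller a controller object from [reflex_controller()],
#'   [constant_controller()], or `NULL` for a passive rollout.
#' @param duration simulated time, s.
#' @param dt internal integration step, s (default 0.25 ms).
#' @param out_dt output sampling interval, s (default 10 ms, i.e. 100 Hz).
#' @param fall_floor pelvis height (m) below which the rollout is marked
#'   failed.
#' @param qd_cap velocity magnitude (rad/s or m/s) treated as integration
#'   blow-up.
#' @return an `stw_trajectory`: a data.frame of sampled quantities with
#'   attributes `status` ("ok", "fell" or "blowup"), `model_mass` and
#'   `t_end`.
#' @export
integrate_rollout <- function(model, state, controller = NULL, duration,
                              dt = 2.5e-4, out_dt = 0.01, fall_floor = 0.4,
                              qd_cap = 50) {
  stopifnot(dt > 0, duration >= 0)
  cm <- compile_model(model)
  ctl <- build_controller_list(controller, model)
  act0 <- if (!is.null(state$act)) state$act else
    rep(0.02, length(cm$fmax))
  res <- .simulate_cpp(cm, ctl, as.numeric(state$q), as.numeric(state$qd),
                       as.numeric(act0),
                       list(dt = dt, out_dt = out_dt, duration = duration,
                            fall_floor = fall_floor, qd_cap = qd_cap))
  traj <- as.data.frame(res$data)
  names(traj) <- res$colnames
  attr(traj, "status") <- res$status
  attr(traj, "t_end") <- res$t_end
  attr(traj, "model_mass") <- model$total_mass
  attr(traj, "gravity") <- model$gravity
  class(traj) <- c("stw_trajectory", "data.frame")
  traj
}

#' Body weight of a model in newtons
#'
#' @param model an `stw_model`.
#' @return total mass times gravitational acceleration, N.
#' @export
body_weight <- function(model) model$total_mass * model$gravity
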