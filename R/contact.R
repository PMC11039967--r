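## Hunt-Crossley compliant contact and regularized friction

#' Hunt-Crossley normal force
#'
#' `F = k delta^p (1 + 1.5 c ddelta)` for penetration depth `delta > 0`,
#' zero otherwise, clamped non-negative (contact never pulls). The
#' velocity-dependent amplification is capped at 4x for impact robustness.
#'
#' @param delta penetration depth, m.
#' @param ddelta penetration rate, m/s.
#' @param k stiffness, N/m^p.
#' @param p penetration exponent.
#' @param c damping coefficient, s/m.
#' @return normal force, N.
#' @export
normal_force <- function(delta, ddelta = 0, k = 5e6, p = 1.5, c = 1) {
  vapply(seq_along(delta), function(i)
    .hc_normal_cpp(delta[i], if (length(ddelta) > 1) ddelta[i] else ddelta,
                   k, p, c), 0)
}

#' Regularized Coulomb friction
#'
#' Tangential force `-mu N tanh(v / vreg)`: opposes slip, smooth through
#' zero slip, and saturates at `mu N` for large slip velocities.
#'
#' @param normal normal force, N (>= 0).
#' @param slip_velocity tangential velocity of the contact point, m/s.
#' @param mu friction coefficient.
#' @param vreg regularization velocity scale, m/s.
#' @return friction force, N (sign opposes slip).
#' @export
friction_force <- function(normal, slip_velocity, mu, vreg = 0.05) {
  stopifnot(all(normal >= 0))
  vapply(seq_along(normal), function(i)
    .friction_cpp(normal[i],
                  if (length(slip_velocity) > 1) slip_velocity[i]
                  else slip_velocity, mu, vreg), 0)
}

#' Evaluate all contact elements at a state
#'
#' Computes per-sphere contact forces (world frame) against the ground plane
#' and the chair box, plus the total ground and chair vertical loads. The
#' total chair load reaching zero defines seat-off in the event detector.
#'
#' @param model an `stw_model`.
#' @param q,qd state.
#' @return list with `forces` (n x 2 matrix, fx/fy per sphere), `points`
#'   (contact application points), `ground_fy` and `chair_fy` totals in N.
#' @export
chair_contact <- function(model, q, qd = numeric(model_nq(model))) {
  out <- .contact_eval_cpp(compile_model(model), as.numeric(q),
                           as.numeric(qd))
  colnames(out$forces) <- c("fx", "fy")
  out
}
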