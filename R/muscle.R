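## Hill-type muscle-tendon unit: curves, activation dynamics, mass and
## metabolic energy rates. Thin wrappers over the engine's evaluators so the
## rollout loop and these functions share one implementation.

#' Active force-length curve
#'
#' Gaussian curve `exp(-((l-1)/w)^2)` in normalized fiber length; exactly 1
#' at optimal length.
#'
#' @param lt normalized fiber length (fiber length / optimal fiber length).
#' @param width Gaussian width parameter.
#' @return force scale factor in [0, 1].
#' @export
force_length <- function(lt, width = muscle_constants()$fl_width) {
  .fl_curve_cpp(as.numeric(lt), width)
}

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric side (zero force at maximal shortening),
#' smooth saturating eccentric branch with a configurable plateau; exactly 1
#' at zero velocity and slope-continuous across it.
#'
#' @param vt normalized fiber velocity in optimal fiber lengths per second
#'   divided by vmax (negative = shortening).
#' @param shape concentric shape parameter.
#' @param ecc eccentric plateau.
#' @return force scale factor.
#' @export
force_velocity <- function(vt, shape = muscle_constants()$fv_shape,
                           ecc = muscle_constants()$fv_ecc) {
  .fv_curve_cpp(as.numeric(vt), shape, ecc)
}

#' Passive force-length curve
#'
#' Exponential passive elasticity engaging above optimal fiber length,
#' normalized to 1 at 60% strain, capped at 3 for numerical robustness.
#'
#' @param lt normalized fiber length.
#' @return passive force as a fraction of maximum isometric force.
#' @export
force_passive <- function(lt) .fp_curve_cpp(as.numeric(lt))

#' One step of first-order activation dynamics
#'
#' `da/dt = (u - a) / tau` with the activation time constant when excitation
#' exceeds activation and the (slower) deactivation constant otherwise;
#' result clamped to [0, 1].
#'
#' @param u excitation in [0, 1].
#' @param a current activation in [0, 1].
#' @param dt step, s.
#' @param tau_act,tau_deact time constants, s.
#' @return updated activation.
#' @export
activation_step <- function(u, a, dt, tau_act = muscle_constants()$tau_act,
                            tau_deact = muscle_constants()$tau_deact) {
  stopifnot(u >= 0, u <= 1, a >= 0, a <= 1)
  .activation_step_cpp(u, a, dt, tau_act, tau_deact)
}

#' Muscle-tendon force under the rigid-tendon Hill model
#'
#' `F = fmax (a fL(l) fV(v) + fP(l))` with normalized fiber length
#' `l = (L - lslack)/lopt` (floored at 0.01 when the unit is slack), always
#' non-negative.
#'
#' @param mdef one row of the model's muscle table (or any list with fields
#'   `fmax`, `lopt`, `lslack`, `vmax`).
#' @param L muscle-tendon length, m.
#' @param v muscle-tendon lengthening velocity, m/s.
#' @param a activation in [0, 1].
#' @param constants muscle constants, see [muscle_constants()].
#' @return force in N.
#' @export
mtu_force <- function(mdef, L, v, a, constants = muscle_constants()) {
  stopifnot(L > 0)
  .mtu_force_cpp(mdef$fmax, mdef$lopt, mdef$lslack, mdef$vmax, L, v, a,
                 constants$fl_width, constants$fv_shape, constants$fv_ecc)
}

#' Muscle mass from strength and architecture
#'
#' Mass = (fmax / specific tension) x density x optimal fiber length, with
#' PCSA in cm^2, fiber length in cm and density in g/cm^3. Scaling fmax by s
#' scales the mass by exactly s, which couples simulated weakness to the
#' metabolic cost model.
#'
#' @inheritParams mtu_force
#' @return mass in kg.
#' @export
muscle_mass <- function(mdef, constants = muscle_constants()) {
  .muscle_mass_cpp(mdef$fmax, mdef$lopt, constants$specific_tension,
                   constants$density)
}

#' Metabolic energy rates of a muscle
#'
#' Activation heat, maintenance heat, shortening heat and positive mechanical
#' work rate. Activation and maintenance heat are proportional to muscle
#' mass (hence to maximum isometric force); shortening heat and work rate
#' are driven by fiber force and shortening velocity and vanish during
#' lengthening. All four rates are non-negative.
#'
#' @param signals list with `a` (activation), `F` (fiber force, N), `v`
#'   (fiber lengthening velocity, m/s) and `lt` (normalized fiber length).
#' @inheritParams mtu_force
#' @return named numeric vector `(Adot, Mdot, Sdot, Wdot)` in W.
#' @export
metabolic_rates <- function(signals, mdef, constants = muscle_constants()) {
  .metabolic_rates_cpp(signals$a, signals$F, signals$v, signals$lt,
                       mdef$fmax, mdef$lopt, constants$specific_tension,
                       constants$density, constants$fl_width)
}
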