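---
title: "Predictive sit-to-walk simulation: model, controller and objective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive sit-to-walk simulation: model, controller and objective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwsim)
```

# The question the package asks

People with unilateral knee osteoarthritis commonly rise from a chair with
more trunk flexion than healthy controls. Two explanations circulate in the
clinical literature: the quadriceps are too weak, so the trunk is thrown
forward to reduce the knee extension demand; or the movement is reorganized
to keep the painful knee's load below a tolerable level. Experiments cannot
separate the two, because strength and pain co-occur in patients. A
predictive simulation can: it synthesizes the movement *de novo* from a
musculoskeletal model, a reflex control policy and a movement objective,
so weakness (a plant change) and pain avoidance (an objective change) can
be imposed separately and the resulting strategies compared.

`stwsim` implements that experiment end to end: a planar
neuromusculoskeletal model that sits on a chair and walks away, a two-state
reflex standing-up controller handing over to a reflex gait controller,
a composite movement objective, CMA-ES optimization of all controller
parameters, and the two condition sweeps — bilateral vasti weakness
(80% to 40% of nominal strength) and stepping-knee peak-load thresholds
(4, 3, 2 body weights).

# The plant

## Skeleton

The body is a planar (sagittal) articulated rigid-body tree: pelvis (3-DOF
planar free joint to the ground), two thighs, shanks and feet (pin joints at
hips, knees, ankles), a lumbar segment and an upper torso with head and
arms lumped (1-DOF lumbar and thoracic joints). That gives 11 generalized
coordinates. Inertial parameters follow de-Leva-style mass fractions scaled
to 75 kg and 1.80 m; because the model has no arm segments, the arm mass is
folded into the upper torso so whole-body mass and the location of the
upper-body center of mass remain realistic.

Angle conventions are fixed package-wide and chosen so clinical quantities
read off directly: forward lean is positive for the pelvis, hip flexion is
positive, knee extension is 0 with flexion negative, ankle dorsiflexion is
positive, and the lumbar/thoracic coordinates are forward-flexion-positive.
Trunk flexion — the paper-level outcome — is then simply
`pelvis_tilt + lumbar + thoracic`. Published joint-range conventions that
count lumbar *extension* positive map onto this convention by a sign flip;
the lumbar range of motion used in the objective, 0 to 50 degrees of
flexion, is the same physical range.

Forward dynamics is computed from the joint-space equations of motion
`M(q) qdd = Q - bias(q, qd)` assembled by Jacobian projection
(`M = sum_i J_i' m_i J_i`, bias from the velocity-product accelerations of
each segment), and integrated with a fixed-step semi-implicit Euler scheme
at `dt = 0.25 ms`, sampled at 100 Hz. The scheme is symplectic: on an
unactuated pendulum the mechanical energy drifts by less than 0.1% over
5 s (this is a test). The step size was chosen for the stiffness of the
contact; the friction regularization (below) is the binding constraint.

## Muscles

Twenty Hill-type muscle-tendon units actuate the legs, ten per side:
iliopsoas, gluteus maximus, adductor magnus, rectus femoris, vasti,
hamstrings, biceps femoris short head, gastrocnemius, soleus and tibialis
anterior. A nine-muscle leg is the common planar roster; the adductor
magnus (a strong extra hip extensor in several published lower-limb models)
is the tenth that brings the total to the 20 units of the reference
morphology.

Muscle paths are constant-moment-arm abstractions: each unit has a signed
moment arm about the coordinates it spans, and its length is
`L(q) = L0 - sum_j r_j q_j`. The moment arm therefore equals `-dL/dq`
exactly — the moment-arm/length-gradient consistency property is tested by
finite differences — and the muscle force enters the dynamics as the
generalized force `F r_j`, which is energy-consistent with the length
model. Arms are typical adult values (e.g. 4.5 cm vasti at the knee,
4.8 cm soleus at the ankle).

The contraction model is rigid-tendon Hill: normalized fiber length
`l = (L - lslack)/lopt`, Gaussian active force-length (width 0.45), a Hill
hyperbola force-velocity curve (shape 0.25, eccentric plateau 1.4, built
slope-continuous at zero velocity), and an exponential passive element
engaging above optimal length. `fL(1) = 1` and `fV(0) = 1` hold exactly.
Excitation-to-activation dynamics are first order with 10 ms activation
and 40 ms deactivation constants, integrated with the exact exponential
update so the closed-form response is reproduced to machine precision.

With a rigid tendon the fiber absorbs the whole joint excursion, so the
*tendon-length calibration matters*: each muscle's `L0` is set so its
fiber sits at optimal length in a muscle-specific reference pose
(deep knee flexion for the vasti — human knee extension torque peaks
around 60-70 degrees of flexion — near-neutral for the plantarflexors,
moderate hip flexion for the hip muscles). A single shared reference pose
is not workable: it either parks the vasti on the passive curve in sitting
(kilonewtons of unintended passive knee-extension force that push the
model backward off the chair) or makes them uselessly short in standing.
This is the one place where the rigid-tendon simplification required a
modeling decision with visible behavioral consequences.

## Muscle mass and metabolic energy

Muscle mass is estimated as
`(fmax / sigma) * rho * lopt` with specific tension
`sigma = 25 N/cm^2` and density `rho = 1.0597 g/cm^3` (PCSA in cm²,
fiber length in cm); a 2500 N, 10 cm muscle weighs 1.0597 kg. The
metabolic model returns four non-negative rates: activation heat
`133 m a`, maintenance heat `74 m a fL(l)`, shortening heat
`0.25 F vs` and positive mechanical work `F vs` (`vs` = shortening
speed, zero when lengthening) — mass-weighted functional forms in the
style of the standard muscle-energetics models, with the coefficients
recorded here and in the config. Because activation and maintenance heat
scale with muscle mass, and mass scales with maximum isometric force,
*weakening the vasti automatically cheapens them metabolically* — the
weakness conditions rescale mass through the same formula, which keeps
the energy term honest.

## Contact

Feet-ground and buttocks-chair contact use Hunt-Crossley spheres:
`F = k d^1.5 (1 + 1.5 c dd)` clamped non-negative, with the
velocity-dependent amplification capped at 2x for impact robustness.
Ground stiffness is 1e6 N/m^1.5 and chair stiffness 2e5 N/m^1.5 with
damping `c = 2 s/m`; these were chosen so static scenes settle
overdamped — a settled seated body carries chair + ground load equal to
body weight within far less than the 1% test tolerance. Friction is
regularized Coulomb, `-mu N tanh(v / 0.15 m/s)`; the band width is set by
explicit-integration stability for the light feet (a narrower band makes
the friction force a stiff viscous element that flip-flops at the step
frequency). Two spheres per foot (heel, forefoot) allow a toe-roll; two
buttock spheres and one mid-thigh sphere per side meet a chair box whose
pan extends under the thighs, with a 2 cm lateral force fade at the
edges so seat-off is smooth. The thigh spheres matter mechanically: the
seat must anchor the thighs, otherwise the reaction torque of a fast
trunk-flexion drive rocks the pelvis backward and swings the unloaded
feet forward. Seat-pan height defaults to 0.46 m (a standard chair; the
reference publications give no number).

# The controller

## Standing up

The standing-up controller has two states with independent gains; the
transition time is an optimized parameter. Each muscle's excitation is

```
u = clamp01( KC + KL+ max(0, L - lo) + KF+ F - KF- F_antagonist
             + Kp (theta - theta0) + Kv thetad )
```

with `L` the normalized fiber length delayed by the muscle's neural
latency, `F` the normalized force, `F_antagonist` the force of a fixed
antagonist partner (vasti-hamstrings, tibialis-soleus,
gluteals-iliopsoas, ...), and `theta` the pelvis tilt — the vestibular
channel. Vestibular gains attach to the hip-spanning muscles and, as an
ankle balance strategy, to soleus and tibialis anterior; the lumbar and
thoracic joints are driven by PD torque actuators (a proxy for the absent
trunk musculature) whose setpoints and gains belong to the parameter
vector. Neural latencies default to 10 ms (hip and trunk-spanning),
20 ms (knee) and 35 ms (ankle muscles), monotone in conduction distance;
delayed signals are linearly interpolated from per-step ring buffers.

In the optimized solutions state 1 is a *weight-shift* state (trunk
flexion builds forward momentum while the knees stay quiet) and state 2
an *extension* state (knee/hip extensor drive plus vestibular balance).
That division is not imposed — both states expose the full gain set — but
the initial guess seeds it, mirroring how the movement is described
clinically.

## Gait

From the (optimized) handover time onward a reflex gait controller takes
over, in the style of the well-known planar reflex walking models: each
leg runs a five-state machine (early stance, late stance = trailing double
support, liftoff, swing, landing) keyed on its ground load relative to an
optimized stance-load threshold and on hip angle; muscles receive
phase-gated constant, length-, force- and vestibular-feedback
contributions (positive plantarflexor force feedback in stance, tibialis
length feedback with soleus inhibition for foot clearance, hip-flexor
drive in liftoff/swing, hamstring/gluteal landing preparation, vasti
inhibition near knee overextension). The stepping leg is the left leg,
fixed, matching the clinical observation that patients step out with the
affected side first.

## Parameter vector

All free scalars — both standing states, the schedule, and the gait block
— flatten into one ordered vector with per-entry bounds and initial
standard deviations (10% of the box width). The default layout has
`r nrow(stwsim::controller_layout())` parameters; gains are shared
bilaterally and the gait block is shared across legs. A fully
side-specific, per-muscle-delay variant in the spirit of the reference
implementation would multiply this towards the ~550 parameters reported
there; the sharing is a deliberate reduction that keeps desk-scale
optimization effective, and the package reports its own count rather than
claiming equality. Parameters round-trip losslessly between the flat
vector and the structured controller (`pack_params()`/`unpack_params()`)
and serialize to diffable plain-text files.

# The objective

The total cost is a sum of hard movement measures, each zero on a
satisfying movement, plus a weighted effort estimate:

* **Gait velocity**: squared shortfall of the average forward velocity
  over the gait phase (first heel strike to the end) below 0.8 m/s — the
  minimum speed regarded as a realistic clinical gait. Rollouts that
  never reach gait receive the term's maximum-penalty regime.
* **Joint ranges**: time-integrated excursion of lumbar (0..50 deg
  flexion), thoracic (±15 deg), pelvis tilt (−30..+50 deg forward) and
  ankle (±60 deg) beyond their ranges.
* **Knee limit force**: the knee carries a passive 500 N·m/rad limit
  spring outside 120 deg flexion / 10 deg extension *inside the
  dynamics*; the objective integrates the recorded spring force.
* **Head acceleration**: integrated excess above 1 m/s², a comfort/gaze
  stabilization criterion.
* **Effort**: `0.01 Jmb + 0.1 Jact + 0.0003 JT`, where `Jmb` integrates
  the summed metabolic rate (normalized by body mass during stand-up and
  by mass × distance — a cost of transport — during gait), `Jact`
  integrates summed cubed activations, and `JT` integrates squared
  lumbar and thoracic actuator torques (the proxy for absent trunk
  muscles). When all hard penalties reach zero, this weighted sum is the
  sole non-zero term; the weights are the published empirical setting.
* **Pain avoidance** (pain conditions only): the stepping-knee load
  integrated above `threshold × BW` over the whole movement, zero once
  the peak stays below the threshold.
* **Progress shaping**: failed rollouts (fall, blow-up) cost a 10,000
  floor plus a term in the missing forward distance; completed rollouts
  that end below standing pelvis height or short of the travel target
  pay a small shaping cost that vanishes on a full sit-to-walk. Without
  this, "remain seated" and "stand quietly" are indistinguishable to the
  optimizer and the standing basin is never found.

Joint "load" is the resultant joint reaction force — the rigid-body
constraint force from a subtree Newton-Euler balance plus the compressive
contribution of the muscles spanning the joint — expressed in body
weights (735.75 N for the default model). With torque-style muscle
application the constraint force alone would miss the dominant
muscle-compression component, which is why the spanning-muscle forces are
added; this matches how joint contact loads are reported in the reference
musculoskeletal tooling.

# Optimization

CMA-ES in the standard `(mu/mu_w, lambda)` formulation with cumulative
step-size adaptation and rank-one/rank-mu covariance updates, implemented
in the package (no suitable R implementation is available in the
supported environment) and validated against convex benchmarks: the 10-D
sphere reaches 1e-8 within 300 generations at population 10, the
published population size. The search runs in box-normalized coordinates
(`sigma0` = 0.05 of the box) with candidates projected onto the bounds for
evaluation. Runs are bit-reproducible given a seed; "parallel"
optimizations are independent seeded restarts whose best is kept, so
results are identical to serial execution.

Condition sweeps are warm-started: the neutral solution seeds the 80%
condition, whose solution seeds 70%, and so on (likewise 4 BW → 3 BW →
2 BW), replicating a progressive capacity decline and keeping desk-scale
budgets effective. A condition whose best rollout never reaches seat-off
is flagged `no_solution` ("unable to rise unaided") together with the
budget under which that judgment was made, since exhausted budget and
true infeasibility cannot be distinguished from a failed search alone.

# Desk scale versus full scale

The package distinguishes two presets. `full_preset()` frees every
parameter over a 6 s horizon — the setting in which the headline numbers
of the motivating study (multi-hour, many-thousand-generation searches)
live. `desk_preset()` is the reduced setting used by the package's own
directional experiments and acceptance checks: a 3 s horizon (stand-up
plus gait initiation), the gait block frozen at the shipped neutral
solution, and optimization restricted to the standing states and
schedule. The shipped neutral controller (`neutral_warm_start()`, plain
text under `inst/extdata/`) was produced by the package's own staged
optimization of the neutral condition and is the declared starting point
of every chain. Desk-scale sweeps are run at population 10 with 25
generations per condition (250 rollouts of 3 s at a 0.25 ms step), the
problem size the package's own acceptance checks use; the claim they
support is *directional* (trend signatures across conditions), never
numerical agreement with the full-scale study. At this scale the
optimized movement is a momentum-transfer rise that reliably reaches
seat-off and gait-initiation events; a statically balanced stand and
steady walking lie beyond these budgets (the objective's fall costs wall
off the standing basin from a population-10 search). That is why the
directional checks anchor on seat-off-based measures, and why a strict
condition-pair monotonicity check can fail at desk scale even when the
underlying contrast (for instance stepping-knee unloading and
ipsilateral VAS+HAM suppression under the pain cost) is large and
systematic.

The synthetic reference envelopes (`synthetic_envelopes()`) deserve a
caveat: they are smooth seeded bands that *emulate the look* of
experimental sEMG envelopes for plot overlays and plotting tests. They
carry no experimental information, are labeled synthetic wherever drawn,
and nothing in the analysis depends on them.

# Numerical choices and degenerate inputs

* Contact stiffnesses, the 2x cap on Hunt-Crossley velocity
  amplification, and the 0.15 m/s friction band are stability-driven
  choices, validated by the static force-balance properties (settled
  loads equal weight within 1%).
* Event detection uses a 5 N threshold with 50 ms debounce, because
  compliant contact never reaches exactly zero; sub-debounce flickers do
  not create events (tested).
* The seated initial state solves a small leg IK (feet tucked, hips near
  the chair front edge) with ~1 cm buttock penetration and ~3 mm foot
  penetration so the start is near contact equilibrium.
* Fall detection (pelvis below 0.4 m) and a 50 rad/s velocity cap mark a
  rollout failed rather than raising an error, so the optimizer can price
  it.
* Zero-duration rollouts return exactly the initial state; muscle fiber
  lengths are floored at 1% of optimal when a unit goes slack.

# Known limitations

Planar dynamics only: no lateral trunk lean, no arm support — the very
compensations unilateral-OA patients also use — so asymmetrical load
redistribution through the frontal plane is outside the model, as in the
motivating study. Muscle paths are constant-arm abstractions; joint loads
inherit that approximation. The thigh-chair interface is two spheres on a
box, so thighs do not roll over the seat edge and the contact period
around seat-off is shortened. The gait controller is tuned for gait
initiation over a short horizon at desk scale; steady-state gait economy
is not a claim this package makes. Finally, desk-scale optimization
budgets find local, not global, optima — which is precisely why condition
sweeps are warm-started and why conclusions are drawn from trends, with
the full-scale preset available for longer searches.
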