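# stwsim — predictive reflex-controlled sit-to-walk simulation

`stwsim` asks a clinical mechanism question with a physics simulation: when
people with unilateral knee osteoarthritis stand up with more trunk
flexion, is that because their knee extensors are weak, or because they are
reorganizing the movement to keep the painful knee's load down? Experiments
cannot separate the two; a predictive simulation can, by imposing weakness
(a plant change) and pain avoidance (an objective change) separately and
re-optimizing the movement each time.

The package implements the full experiment in R with a compiled core:

* a planar 11-DOF musculoskeletal body (75 kg, 1.80 m) actuated by 20
  Hill-type muscle-tendon units, with Hunt–Crossley chair and ground
  contact;
* a two-state reflex standing-up controller (monosynaptic and antagonistic
  force/length feedback, vestibular pelvis-tilt feedback, lumbar/thoracic
  PD torques) handing over to a reflex gait controller with a per-leg
  five-state machine;
* a composite movement objective
  `J = J_vel + J_range + J_kneelimit + J_headacc +
  0.01 J_mb + 0.1 J_act + 0.0003 J_T (+ J_pain)`
  whose hard terms reach zero on a satisfying movement (gait velocity
  >= 0.8 m/s, joint ranges, 500 N·m/rad knee limit spring, 1 m/s² head
  acceleration), with metabolic energy `J_mb` (activation + maintenance +
  shortening heat + positive work, mass-weighted), cubed activations
  `J_act`, trunk torques `J_T`, and an optional pain-avoidance cost that
  integrates the stepping-knee load above a threshold in body weights;
* CMA-ES (population 10) over the flat controller parameter vector, with
  seeded restarts and warm-started condition chains;
* the two condition sweeps: bilateral vasti maximum-isometric-force
  scaling 0.8/0.7/0.6/0.5/0.4 (muscle metabolic mass rescales with it) and
  stepping-knee peak-load thresholds 4/3/2 BW (left leg steps first);
* movement measures: seat-off / toe-off / heel-strike detection (5 N,
  50 ms debounce), trunk flexion (pelvis tilt + lumbar + thoracic, forward
  positive), joint loads in body weights, timing, peak activations; CSV,
  OpenSim `.sto`, JSON and PNG writers.

## Worked example

Simulate the neutral condition with the shipped pre-optimized controller
and summarize it:

```r
library(stwsim)
model <- build_default_model()
model
#> <stw_model> 9 segments, 11 DOF, 20 muscles, 75.0 kg, 1.80 m

ctrl <- reflex_controller(neutral_warm_start())
traj <- integrate_rollout(model, seated_state(model), ctrl,
                          duration = 3.0)
metrics <- movement_metrics(traj)
metrics
#> <metrics> trunk flexion at seat-off: 27.0 deg, max: 2.8 deg
#>   time to first heel strike (stepping leg): 0.73 s
#>   peak loads [BW]: hip_r 3.74, hip_l 3.74, knee_r 5.46, knee_l 5.46,
#>   ankle_r 3.44, ankle_l 3.44
```

The metrics report trunk flexion at seat-off in degrees (the sum of pelvis
tilt, lumbar and thoracic angles against the global vertical — 27.0° here:
the model leans into the rise and leaves the seat at 0.51 s), the time
from movement onset to the first heel strike of the stepping (left) leg,
and peak joint loads in body weights (1 BW = 735.75 N for this model; the
peak knee load of 5.5 BW occurs just after seat-off). The desk-scale
movement is a momentum-transfer rise through seat-off and gait initiation;
see the methods vignette for what this scale does and does not show.

A desk-scale condition sweep (weakness chain warm-started from neutral,
then the pain chain) runs through `run_study()`:

```r
study <- run_study(grid = study_grid(),
                   config = optimization_config(max_generations = 8,
                                                seed = 1),
                   preset = desk_preset())
study_summary(study)
```

`study_summary()` returns one row per condition with trunk flexion at
seat-off, peak knee/ankle loads, timing, the best objective value, and the
`no_solution` flag ("unable to rise unaided") that severe weakness is
expected to raise. Desk-scale runs support directional claims (trends
across conditions), not the numerical values of multi-hour full-scale
optimizations; see the methods vignette
(`vignettes/sit-to-walk-methods.Rmd`) for what each scale does and does
not show.

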