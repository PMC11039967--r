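## Model definition: segments, joints, muscles, contact elements.
##
## Geometry conventions (fixed package-wide):
##  * sagittal plane, x forward, y up; angles "forward-lean positive"
##    (a positive segment angle tips the segment top forward);
##  * generalized coordinates: pelvis_x [m], pelvis_y [m], pelvis_tilt [rad,
##    anterior tilt positive], hip_r, knee_r, ankle_r, hip_l, knee_l, ankle_l,
##    lumbar, thoracic [rad];
##  * hip flexion positive, knee extension 0 / flexion negative, ankle
##    dorsiflexion positive, lumbar/thoracic forward flexion positive, so
##    trunk flexion = pelvis_tilt + lumbar + thoracic directly.

DOF_NAMES <- c("pelvis_x", "pelvis_y", "pelvis_tilt",
               "hip_r", "knee_r", "ankle_r",
               "hip_l", "knee_l", "ankle_l",
               "lumbar", "thoracic")

MUSCLE_GROUPS <- c("ilpso", "gmax", "adm", "rf", "vas",
                   "ham", "bfsh", "gas", "sol", "ta")

#' Default muscle constants
#'
#' Specific tension 25 N/cm^2 and density 1.0597 g/cm^3 enter the muscle-mass
#' estimate used by the metabolic model; activation/deactivation time
#' constants govern first-order excitation-activation dynamics.
#'
#' @return named list of muscle constants.
#' @export
muscle_constants <- function() {
  list(specific_tension = 25,     # N/cm^2
       density = 1.0597,          # g/cm^3
       tau_act = 0.010,           # s
       tau_deact = 0.040,         # s
       fl_width = 0.45,           # Gaussian active force-length width
       fv_shape = 0.25,           # Hill hyperbola shape
       fv_ecc = 1.4)              # eccentric force plateau
}

# Anthropometric segment table for a given stature/mass, de-Leva-style mass
# fractions with arms lumped into the upper trunk (the model has no arm
# segments). Lengths scale linearly with height.
default_segment_params <- function(total_mass = 75, height = 1.80) {
  s <- height / 1.80
  thigh_l <- 0.441 * s
  shank_l <- 0.4428 * s
  frac <- c(pelvis = 0.142, lumbar_trunk = 0.139, torso = 0.397,
            thigh = 0.100, shank = 0.0465, foot = 0.0145)
  m <- total_mass * frac
  list(thigh_l = thigh_l, shank_l = shank_l,
       foot_ankle_h = 0.08 * s, heel_x = -0.06 * s, toe_x = 0.20 * s,
       lumbar_l = 0.18 * s, head_y = 0.45 * s,
       masses = m,
       inertias = c(pelvis = 0.08, lumbar_trunk = 0.05, torso = 1.5,
                    thigh = m[["thigh"]] * (0.3 * thigh_l)^2,
                    shank = m[["shank"]] * (0.3 * shank_l)^2,
                    foot = 0.005))
}

# Default per-leg muscle table. Paths are constant-moment-arm abstractions of
# the usual lower-limb geometry; columns r_hip/r_knee/r_ankle are moment arms
# in m about the leg coordinates, signed so that a positive arm drives the
# coordinate positive (hip flexion +, knee extension +, dorsiflexion +).
# qref_* give the per-muscle reference pose at which the fiber sits at
# optimal length; they place each muscle's working range physiologically
# (knee extensors strongest in deep flexion, plantarflexors near neutral)
# under the rigid-tendon model.
default_muscle_table <- function() {
  data.frame(
    group  = MUSCLE_GROUPS,
    fmax   = c(1500, 1550, 880, 1000, 4500, 2600, 800, 1600, 2800, 1000),
    lopt   = c(0.100, 0.140, 0.130, 0.081, 0.120, 0.105, 0.120,
               0.060, 0.050, 0.098),
    lslack = rep(0.20, 10),
    vmax   = rep(10, 10),  # optimal fiber lengths per second
    delay  = c(0.010, 0.010, 0.010, 0.020, 0.020, 0.010, 0.020,
               0.035, 0.035, 0.035),
    r_hip  = c(0.040, -0.062, -0.055, 0.042, 0, -0.060, 0, 0, 0, 0),
    r_knee = c(0, 0, 0, 0.040, 0.045, -0.030, -0.030, -0.020, 0, 0),
    r_ankle = c(0, 0, 0, 0, 0, 0, 0, -0.045, -0.048, 0.040),
    qref_hip = c(0.4, 1.0, 1.0, 0.8, 0, 0.8, 0, 0, 0, 0),
    qref_knee = c(0, 0, 0, -1.0, -1.22, -0.8, -0.8, -0.3, 0, 0),
    qref_ankle = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    antagonist = c("gmax", "ilpso", "ilpso", "ham", "ham",
                   "vas", "vas", "ta", "ta", "sol"),
    stringsAsFactors = FALSE
  )
}

#' Default model configuration
#'
#' Assembles the configuration record (segment, muscle, contact and joint
#' tables) for the default planar body: total mass 75 kg, stature 1.80 m,
#' 11 degrees of freedom, 20 muscle-tendon units, two contact spheres per
#' foot, two buttock spheres and a chair box with a 0.46 m seat pan.
#'
#' @param total_mass body mass in kg.
#' @param height stature in m.
#' @param seat_height chair seat-pan height in m.
#' @return a nested list understood by [build_default_model()].
#' @export
default_model_config <- function(total_mass = 75, height = 1.80,
                                 seat_height = 0.46) {
  list(total_mass = total_mass, height = height, seat_height = seat_height,
       gravity = 9.81,
       segments = default_segment_params(total_mass, height),
       muscles = default_muscle_table(),
       constants = muscle_constants(),
       contact = list(ground_k = 1e6, ground_mu = 0.9,
                      chair_k = 2e5, chair_mu = 0.7,
                      exponent = 1.5, damping = 2.0, vt_reg = 0.15))
}

#' Build the default sit-to-walk model
#'
#' Constructs and validates the full model definition from a configuration
#' record: 9 segments (pelvis, two thighs/shanks/feet, lumbar trunk, upper
#' torso with head and arms lumped), one planar free joint pelvis-ground,
#' eight pin joints, 20 Hill-type muscles and the Hunt-Crossley contact set.
#'
#' @param config configuration list from [default_model_config()] (or read
#'   back from a YAML model file via [read_model_config()]).
#' @return an object of class `stw_model`.
#' @export
build_default_model <- function(config = default_model_config()) {
  sp <- config$segments
  m <- sp$masses; I <- sp$inertias
  if (any(unlist(m) <= 0)) stop("segment masses must be positive")
  if (any(unlist(I) <= 0)) stop("segment inertias must be positive")

  seg <- function(name, mass, inertia, com, parent, jkind, ap, ac, sgn, dof) {
    list(name = name, mass = mass, inertia = inertia, com = com,
         parent = parent, jkind = jkind, ap = ap, ac = ac, sgn = sgn,
         dof = dof)
  }
  thl <- sp$thigh_l; shl <- sp$shank_l
  segments <- list(
    seg("pelvis", m[["pelvis"]], I[["pelvis"]], c(-0.04, 0.05),
        NA, "planar_free", c(0, 0), c(0, 0), 1, "pelvis_x"),
    seg("thigh_r", m[["thigh"]], I[["thigh"]], c(0, -0.433 * thl),
        "pelvis", "pin", c(0, 0), c(0, 0), -1, "hip_r"),
    seg("shank_r", m[["shank"]], I[["shank"]], c(0, -0.433 * shl),
        "thigh_r", "pin", c(0, -thl), c(0, 0), -1, "knee_r"),
    seg("foot_r", m[["foot"]], I[["foot"]], c(0.06, -0.05),
        "shank_r", "pin", c(0, -shl), c(0, 0), -1, "ankle_r"),
    seg("thigh_l", m[["thigh"]], I[["thigh"]], c(0, -0.433 * thl),
        "pelvis", "pin", c(0, 0), c(0, 0), -1, "hip_l"),
    seg("shank_l", m[["shank"]], I[["shank"]], c(0, -0.433 * shl),
        "thigh_l", "pin", c(0, -thl), c(0, 0), -1, "knee_l"),
    seg("foot_l", m[["foot"]], I[["foot"]], c(0.06, -0.05),
        "shank_l", "pin", c(0, -shl), c(0, 0), -1, "ankle_l"),
    seg("lumbar_trunk", m[["lumbar_trunk"]], I[["lumbar_trunk"]],
        c(0, 0.5 * sp$lumbar_l),
        "pelvis", "pin", c(-0.03, 0.12), c(0, 0), 1, "lumbar"),
    seg("torso", m[["torso"]], I[["torso"]], c(0, 0.22),
        "lumbar_trunk", "pin", c(0, sp$lumbar_l), c(0, 0), 1, "thoracic")
  )

  # per-dof passive elements: viscous damping plus soft anatomical stops;
  # the knee stop is the 500 N m/rad limit spring whose force enters the
  # objective's knee-limit term
  dofs <- data.frame(
    name = DOF_NAMES,
    damping = c(0, 0, 0, 1, 1, 1, 1, 1, 1, 5, 5),
    kpass = 0, qpass = 0,
    klim = c(0, 0, 0, 100, 500, 100, 100, 500, 100, 100, 100),
    qlo  = c(-Inf, -Inf, -Inf,
             -0.35, -2.0944, -1.0472, -0.35, -2.0944, -1.0472, 0, -0.2618),
    qhi  = c(Inf, Inf, Inf,
             2.10, 0.1745, 1.0472, 2.10, 0.1745, 1.0472, 0.8727, 0.2618),
    blim = c(0, 0, 0, 5, 10, 2, 5, 10, 2, 5, 5),
    stringsAsFactors = FALSE
  )

  mt <- config$muscles
  if (nrow(mt) != 10) stop("expected 10 muscle groups per leg")
  muscles <- do.call(rbind, lapply(c("r", "l"), function(side) {
    d <- mt
    d$name <- paste0(d$group, "_", side)
    d$side <- side
    d
  }))
  arms <- matrix(0, nrow = nrow(muscles), ncol = length(DOF_NAMES),
                 dimnames = list(muscles$name, DOF_NAMES))
  for (i in seq_len(nrow(muscles))) {
    side <- muscles$side[i]
    arms[i, paste0("hip_", side)] <- muscles$r_hip[i]
    arms[i, paste0("knee_", side)] <- muscles$r_knee[i]
    arms[i, paste0("ankle_", side)] <- muscles$r_ankle[i]
  }
  # L0 puts the fiber at optimal length in the muscle's own reference pose
  muscles$L0 <- muscles$lslack + muscles$lopt +
    muscles$r_hip * muscles$qref_hip +
    muscles$r_knee * muscles$qref_knee +
    muscles$r_ankle * muscles$qref_ankle

  cc <- config$contact
  sh <- config$seat_height
  # feet: heel + forefoot spheres; chair: two buttock spheres on the pelvis
  # plus one mid-thigh sphere per side (the seat supports the thighs, which
  # anchors the pelvis against trunk-flexion reaction torques while seated)
  contacts <- data.frame(
    segment = c("foot_r", "foot_r", "foot_l", "foot_l", "pelvis", "pelvis",
                "thigh_r", "thigh_l"),
    off_x = c(sp$heel_x - 0.02, sp$toe_x - 0.02,
              sp$heel_x - 0.02, sp$toe_x - 0.02, -0.06, -0.15,
              -0.03, -0.03),
    off_y = c(-sp$foot_ankle_h + 0.03, -sp$foot_ankle_h + 0.025,
              -sp$foot_ankle_h + 0.03, -sp$foot_ankle_h + 0.025,
              -0.045, -0.045, -0.25, -0.25),
    radius = c(0.03, 0.025, 0.03, 0.025, 0.04, 0.04, 0.04, 0.04),
    k = c(rep(cc$ground_k, 4), rep(cc$chair_k, 4)),
    p = cc$exponent, c = cc$damping,
    mu = c(rep(cc$ground_mu, 4), rep(cc$chair_mu, 4)),
    surface = c(rep("ground", 4), rep("chair", 4)),
    side = c("r", "r", "l", "l", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )

  model <- structure(list(
    segments = segments, dofs = dofs, muscles = muscles, arms = arms,
    contacts = contacts,
    chair = list(x0 = -1.2, x1 = -0.10, top = sh),
    constants = config$constants,
    gravity = config$gravity, vt_reg = cc$vt_reg,
    total_mass = sum(vapply(segments, `[[`, 0, "mass")),
    height = config$height,
    head_local = c(0, sp$head_y),
    config = config
  ), class = "stw_model")
  validate_model(model)
  model
}

#' Validate a model definition
#'
#' Checks the structural invariants: positive masses and inertias, exactly
#' one planar free joint, 11 generalized coordinates for the default build,
#' 20 muscle-tendon units, and total mass equal to the sum of segment masses.
#'
#' @param model an `stw_model`.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  masses <- vapply(model$segments, `[[`, 0, "mass")
  if (any(masses <= 0)) stop("validation error: non-positive segment mass")
  if (any(vapply(model$segments, `[[`, 0, "inertia") <= 0))
    stop("validation error: non-positive segment inertia")
  nfree <- sum(vapply(model$segments, `[[`, "", "jkind") == "planar_free")
  if (nfree != 1) stop("validation error: expected exactly one planar_free joint")
  npin <- sum(vapply(model$segments, `[[`, "", "jkind") == "pin")
  ndof <- 3 + npin
  if (ndof != nrow(model$dofs))
    stop(sprintf("validation error: DOF count %d does not match dof table %d",
                 ndof, nrow(model$dofs)))
  if (!is.null(model$muscles) && nrow(model$muscles) != 20)
    stop("validation error: default build requires 20 muscle-tendon units")
  if (abs(model$total_mass - sum(masses)) > 1e-9)
    stop("validation error: total mass does not equal sum of segment masses")
  invisible(model)
}

#' @export
print.stw_model <- function(x, ...) {
  cat(sprintf("<stw_model> %d segments, %d DOF, %d muscles, %.1f kg, %.2f m\n",
              length(x$segments), nrow(x$dofs),
              if (is.null(x$muscles)) 0 else nrow(x$muscles),
              x$total_mass, x$height))
  invisible(x)
}

# Number of generalized coordinates
model_nq <- function(model) nrow(model$dofs)

# Flatten an stw_model into the numeric representation the C++ engine parses.
compile_model <- function(model) {
  segs <- model$segments
  nseg <- length(segs)
  name2idx <- setNames(seq_len(nseg) - 1L, vapply(segs, `[[`, "", "name"))
  dofn <- model$dofs$name
  dof2idx <- setNames(seq_along(dofn) - 1L, dofn)
  jk <- vapply(segs, `[[`, "", "jkind")
  jkind <- ifelse(jk == "planar_free", 0L, ifelse(jk == "pin_ground", 1L, 2L))
  parent <- vapply(segs, function(s)
    if (is.na(s$parent[1])) -1L else unname(name2idx[s$parent]), 0L)
  dof <- vapply(segs, function(s) {
    if (s$jkind == "planar_free") 0L else unname(dof2idx[s$dof])
  }, 0L)
  mus <- model$muscles
  nm <- if (is.null(mus)) 0L else nrow(mus)
  has_idx <- all(c("hip_r", "lumbar") %in% dofn) &&
    any(vapply(segs, `[[`, "", "name") == "torso")
  cm <- list(
    nq = nrow(model$dofs),
    mass = vapply(segs, `[[`, 0, "mass"),
    inertia = vapply(segs, `[[`, 0, "inertia"),
    com = vapply(segs, `[[`, c(0, 0), "com"),
    parent = as.integer(parent), jkind = as.integer(jkind),
    dof = as.integer(dof),
    ap = vapply(segs, `[[`, c(0, 0), "ap"),
    ac = vapply(segs, `[[`, c(0, 0), "ac"),
    sgn = vapply(segs, `[[`, 0, "sgn"),
    damping = model$dofs$damping, kpass = model$dofs$kpass,
    qpass = model$dofs$qpass, klim = model$dofs$klim,
    qlo = model$dofs$qlo, qhi = model$dofs$qhi, blim = model$dofs$blim,
    fmax = if (nm) mus$fmax else numeric(0),
    mpar = model$constants,
    gravity = model$gravity,
    vt_reg = if (is.null(model$vt_reg)) 0.15 else model$vt_reg,
    dof_names = dofn,
    has_idx = has_idx
  )
  if (nm) {
    g2i <- setNames(seq_along(MUSCLE_GROUPS) - 1L, MUSCLE_GROUPS)
    anti <- vapply(seq_len(nm), function(i) {
      j <- which(mus$name == paste0(mus$antagonist[i], "_", mus$side[i]))
      if (length(j) == 1) j - 1L else -1L     # toys may lack the antagonist
    }, 0L)
    cm$lopt <- mus$lopt; cm$lslack <- mus$lslack; cm$vmax <- mus$vmax
    cm$L0 <- mus$L0
    cm$arms <- model$arms
    cm$mgroup <- as.integer(unname(g2i[mus$group]))
    cm$mside <- as.integer(ifelse(mus$side == "r", 0L, 1L))
    cm$antag <- as.integer(anti)
    cm$mdelay <- mus$delay
    cm$mus_names <- mus$name
  } else {
    cm$mus_names <- character(0)
    cm$mgroup <- integer(0); cm$mside <- integer(0); cm$antag <- integer(0)
  }
  ct <- model$contacts
  if (!is.null(ct) && nrow(ct)) {
    cm$cseg <- as.integer(unname(name2idx[ct$segment]))
    cm$coff <- rbind(ct$off_x, ct$off_y)
    cm$crad <- ct$radius; cm$ck <- ct$k; cm$cpow <- ct$p; cm$cdamp <- ct$c
    cm$cmu <- ct$mu
    cm$csurf <- as.integer(ifelse(ct$surface == "ground", 0L, 1L))
    cm$cside <- as.integer(ifelse(is.na(ct$side), -1L,
                                  ifelse(ct$side == "r", 0L, 1L)))
  } else {
    cm$cseg <- integer(0)
  }
  cm$has_chair <- !is.null(model$chair)
  if (cm$has_chair) {
    cm$chair_x0 <- model$chair$x0; cm$chair_x1 <- model$chair$x1
    cm$chair_top <- model$chair$top
  }
  if (has_idx) {
    cm$idx <- c(hip_r = unname(dof2idx[["hip_r"]]),
                knee_r = unname(dof2idx[["knee_r"]]),
                ankle_r = unname(dof2idx[["ankle_r"]]),
                hip_l = unname(dof2idx[["hip_l"]]),
                knee_l = unname(dof2idx[["knee_l"]]),
                ankle_l = unname(dof2idx[["ankle_l"]]),
                lumbar = unname(dof2idx[["lumbar"]]),
                thoracic = unname(dof2idx[["thoracic"]]),
                pelvis_seg = 0L,
                torso_seg = unname(name2idx[["torso"]]))
    cm$head_local <- model$head_local
  }
  cm
}

#' Seated initial state for the sit-to-walk task
#'
#' Places the pelvis near the chair's front edge with ~1 cm of
#' buttock-sphere penetration, both feet flat on the ground and tucked
#' slightly back (shanks leaning backward, ankles dorsiflexed), thighs
#' near-horizontal and the trunk upright. All velocities are zero.
#'
#' @param model an `stw_model`.
#' @param ankle_x forward position of the ankles, m.
#' @param hip_x forward position of the hip joints, m (default sits the
#'   buttocks just behind the chair's front edge).
#' @return list with elements `q`, `qd` and `act` (initial activations).
#' @export
seated_state <- function(model, ankle_x = -0.08, hip_x = -0.28) {
  sp <- model$config$segments
  hip <- c(hip_x, model$chair$top + 0.085 - 0.012)
  ankle <- c(ankle_x, sp$foot_ankle_h - 0.0015)
  dv <- ankle - hip
  d <- sqrt(sum(dv^2))
  th <- sp$thigh_l; sh <- sp$shank_l
  if (d >= th + sh || d <= abs(th - sh))
    stop("seated pose out of reach for the leg geometry")
  a <- (th^2 + d^2 - sh^2) / (2 * d)
  h <- sqrt(th^2 - a^2)
  u <- dv / d
  n <- c(-u[2], u[1]); if (n[1] < 0) n <- -n   # knee bends forward
  knee <- hip + a * u + h * n
  seg_angle <- function(from, to) {           # clockwise-from-vertical
    dxy <- to - from
    atan2(-dxy[1], -dxy[2])
  }
  th_thigh <- seg_angle(hip, knee)
  th_shank <- seg_angle(knee, ankle)
  q <- setNames(numeric(model_nq(model)), model$dofs$name)
  q["pelvis_x"] <- hip[1]; q["pelvis_y"] <- hip[2]
  q["hip_r"] <- q["hip_l"] <- -th_thigh       # theta_thigh = tilt - q_hip
  q["knee_r"] <- q["knee_l"] <- th_thigh - th_shank
  q["ankle_r"] <- q["ankle_l"] <- th_shank    # foot flat on the ground
  list(q = q, qd = setNames(numeric(model_nq(model)), model$dofs$name),
       act = if (is.null(model$muscles)) numeric(0) else
         rep(0.02, nrow(model$muscles)))
}
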