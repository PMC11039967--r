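## Fixtures and synthetic inputs: the default model config file, toy scenes
## with closed-form oracles, the reduced desk-scale preset and synthetic
## reference activation envelopes. Everything is generated in code; no
## external data is required anywhere in the package.

#' Build a toy model from explicit parts
#'
#' Assembles a small `stw_model` (1-2 segments) for oracle scenes; no
#' full-body invariants are enforced.
#'
#' @param segments list of segment records (see [build_default_model()]'s
#'   internals for the fields).
#' @param dofs dof table (name, damping, kpass, qpass, klim, qlo, qhi,
#'   blim).
#' @param muscles,arms optional muscle table and moment-arm matrix.
#' @param contacts,chair optional contact table and chair geometry.
#' @param constants muscle constants.
#' @param gravity m/s^2.
#' @return an `stw_model`.
#' @export
make_toy_model <- function(segments, dofs, muscles = NULL, arms = NULL,
                           contacts = NULL, chair = NULL,
                           constants = muscle_constants(), gravity = 9.81) {
  structure(list(
    segments = segments, dofs = dofs, muscles = muscles, arms = arms,
    contacts = contacts, chair = chair, constants = constants,
    gravity = gravity, vt_reg = 0.15,
    total_mass = sum(vapply(segments, `[[`, 0, "mass")),
    height = NA_real_, head_local = c(0, 0), config = NULL),
    class = "stw_model")
}

toy_seg <- function(name, mass, inertia, com, parent, jkind, ap, ac,
                    sgn = 1, dof = "q1") {
  list(name = name, mass = mass, inertia = inertia, com = com,
       parent = parent, jkind = jkind, ap = ap, ac = ac, sgn = sgn,
       dof = dof)
}

toy_dofs <- function(names, damping = 0) {
  data.frame(name = names, damping = damping, kpass = 0, qpass = 0,
             klim = 0, qlo = -Inf, qhi = Inf, blim = 0,
             stringsAsFactors = FALSE)
}

#' Toy oracle scenes
#'
#' Small scenes, each paired with an executable analytic oracle, used by
#' the dynamics/contact/muscle test suites:
#' \describe{
#'   \item{pendulum}{distributed-mass rod on a world pin; closed-form
#'     `qdd = -(m g d / I_o) sin(q)` and small-amplitude period.}
#'   \item{double_pendulum}{two rods; oracle is an independent Lagrangian
#'     evaluation from hand-written trigonometry.}
#'   \item{lever_muscle}{rod on a pin with one constant-arm muscle;
#'     isometric joint torque equals `F x arm`.}
#'   \item{drop_test}{ball with one contact sphere falling on the ground;
#'     settles at its own weight.}
#'   \item{seated_static}{the full-body model, muscles removed and joints
#'     held by stiff passive springs in the seated pose; chair + ground
#'     vertical load must settle at body weight.}
#' }
#'
#' @return named list of scenes; each has `model`, `q0`, `oracle`
#'   (scene-specific closed form) and a `description`.
#' @export
toy_scenes <- function() {
  scenes <- list()

  m <- 2; L <- 1; d <- 0.5
  Icom <- m * L^2 / 12
  Io <- Icom + m * d^2
  scenes$pendulum <- list(
    model = make_toy_model(
      list(toy_seg("rod", m, Icom, c(0, 0), NA, "pin_ground",
                   ap = c(0, 1.5), ac = c(0, d))),
      toy_dofs("q1")),
    q0 = 0.3,
    oracle = list(
      qdd = function(q) -(m * 9.81 * d / Io) * sin(q),
      period = 2 * pi * sqrt(Io / (m * 9.81 * d)),
      m = m, d = d, Io = Io),
    description = "distributed-mass pendulum, closed-form dynamics")

  m1 <- 1.5; L1 <- 0.8; m2 <- 1.0; L2 <- 0.7
  scenes$double_pendulum <- list(
    model = make_toy_model(
      list(toy_seg("rod1", m1, m1 * L1^2 / 12, c(0, 0), NA, "pin_ground",
                   ap = c(0, 2), ac = c(0, L1 / 2), dof = "q1"),
           toy_seg("rod2", m2, m2 * L2^2 / 12, c(0, 0), "rod1", "pin",
                   ap = c(0, -L1 / 2), ac = c(0, L2 / 2), dof = "q2")),
      toy_dofs(c("q1", "q2"))),
    q0 = c(0.4, -0.25),
    oracle = list(m1 = m1, L1 = L1, m2 = m2, L2 = L2, anchor = c(0, 2)),
    description = "two-rod chain for the independent Lagrangian oracle")

  mus <- data.frame(name = "toy_mus", group = "vas", side = "r",
                    fmax = 1000, lopt = 0.1, lslack = 0.2, vmax = 10,
                    delay = 0.01, antagonist = "vas", L0 = 0.3,
                    stringsAsFactors = FALSE)
  arm <- matrix(0.05, 1, 1, dimnames = list("toy_mus", "q1"))
  scenes$lever_muscle <- list(
    model = make_toy_model(
      list(toy_seg("lever", 1, 0.02, c(0, -0.2), NA, "pin_ground",
                   ap = c(0, 1), ac = c(0, 0))),
      toy_dofs("q1"), muscles = mus, arms = arm),
    q0 = 0,
    oracle = list(arm = 0.05),
    description = "single-muscle lever: isometric torque = F x arm")

  scenes$drop_test <- list(
    model = make_toy_model(
      list(toy_seg("ball", 5, 0.01, c(0, 0), NA, "planar_free",
                   ap = c(0, 0), ac = c(0, 0), dof = "px")),
      toy_dofs(c("px", "py", "rot"), damping = c(0, 0, 0.5)),
      contacts = data.frame(
        segment = "ball", off_x = 0, off_y = 0, radius = 0.1,
        k = 1e5, p = 1.5, c = 1, mu = 0.9, surface = "ground",
        side = "r", stringsAsFactors = FALSE)),
    q0 = c(0, 0.15, 0),
    oracle = list(weight = 5 * 9.81),
    description = "sphere dropped on the ground settles at its weight")

  base <- build_default_model()
  st <- seated_state(base)
  base$muscles <- NULL; base$arms <- NULL
  base$dofs$kpass <- c(0, 0, 50, rep(300, 6), 300, 300)
  base$dofs$qpass <- as.numeric(st$q)
  base$dofs$damping <- c(0, 0, 5, rep(30, 6), 30, 30)
  scenes$seated_static <- list(
    model = base, q0 = st$q,
    oracle = list(weight = base$total_mass * base$gravity),
    description = "passive seated body settles; chair+ground = body weight")

  scenes
}

#' Write the default model configuration file
#'
#' Serializes the default model configuration as YAML; reading it back
#' through [read_model_config()] and [build_default_model()] reproduces
#' the model exactly. Output contains no timestamps, so regeneration is
#' byte-identical.
#'
#' @param path output file.
#' @param config configuration to write.
#' @return the path, invisibly.
#' @export
default_model_file <- function(path, config = default_model_config()) {
  cfg <- config
  cfg$muscles <- as.list(cfg$muscles)
  cfg$segments$masses <- as.list(cfg$segments$masses)
  cfg$segments$inertias <- as.list(cfg$segments$inertias)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path YAML file written by [default_model_file()].
#' @return configuration list for [build_default_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$muscles <- as.data.frame(cfg$muscles, stringsAsFactors = FALSE)
  cfg$segments$masses <- unlist(cfg$segments$masses)
  cfg$segments$inertias <- unlist(cfg$segments$inertias)
  cfg
}

#' Desk-scale simulation preset
#'
#' The reduced setting used by fast directional experiments: a shortened
#' horizon covering stand-up plus the first steps, the default integrator
#' step, and a frozen gait block (only the standing states and the
#' schedule are optimized, warm-started from the shipped neutral
#' solution).
#'
#' @param duration rollout horizon, s.
#' @param dt integration step, s.
#' @param out_dt sampling interval, s.
#' @return list with rollout settings and the `free` parameter-name subset.
#' @export
desk_preset <- function(duration = 3.0, dt = 2.5e-4, out_dt = 0.01) {
  layout <- controller_layout()
  list(duration = duration, dt = dt, out_dt = out_dt,
       free = layout$name[layout$block %in% c("stand1", "stand2",
                                              "schedule")],
       scale = "desk")
}

#' Full-scale simulation preset
#'
#' Longer horizon and every controller parameter free; intended for
#' multi-hour optimizations.
#'
#' @inheritParams desk_preset
#' @return preset list.
#' @export
full_preset <- function(duration = 6, dt = 2.5e-4, out_dt = 0.01) {
  list(duration = duration, dt = dt, out_dt = out_dt, free = NULL,
       scale = "full")
}

#' Neutral warm-start parameters
#'
#' The package ships a pre-optimized neutral sit-to-walk controller (plain
#' text, produced by the package's own optimizer on the neutral condition)
#' used as the starting point of the condition chains. Falls back to the
#' layout's initial values when the file is absent.
#'
#' @return named parameter vector.
#' @export
neutral_warm_start <- function() {
  f <- system.file("extdata", "neutral_params.txt", package = "stwsim")
  if (nzchar(f) && file.exists(f)) read_params(f)
  else default_controller_params()
}

#' Synthetic reference activation envelopes
#'
#' Smooth per-muscle activation bands over normalized movement time,
#' generated from fixed Gaussian-bump bases plus seeded noise. These are
#' synthetic stand-ins for experimental sEMG envelopes, intended only as
#' plot overlays; they carry no experimental information and are labeled
#' synthetic wherever drawn.
#'
#' @param seed RNG seed.
#' @param band half-width of the band around the mean (0 gives a
#'   mean-only envelope).
#' @param n number of time samples over the movement.
#' @return named list (per muscle group) of data.frames with `time_norm`,
#'   `mean`, `lo`, `hi`, all within [0, 1].
#' @export
synthetic_envelopes <- function(seed = 1, band = 0.08, n = 101) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  tt <- seq(0, 1, length.out = n)
  bump <- function(c0, w, h) h * exp(-((tt - c0) / w)^2)
  shapes <- list(
    ilpso = bump(0.55, 0.10, 0.5) + bump(0.85, 0.08, 0.3),
    gmax = bump(0.25, 0.10, 0.5) + bump(0.65, 0.10, 0.25),
    adm = bump(0.25, 0.12, 0.35),
    rf = bump(0.30, 0.10, 0.35) + bump(0.80, 0.08, 0.2),
    vas = bump(0.25, 0.10, 0.7) + bump(0.75, 0.10, 0.25),
    ham = bump(0.30, 0.12, 0.4) + bump(0.90, 0.07, 0.3),
    bfsh = bump(0.55, 0.08, 0.35),
    gas = bump(0.45, 0.10, 0.5) + bump(0.85, 0.08, 0.4),
    sol = bump(0.45, 0.12, 0.55) + bump(0.85, 0.08, 0.45),
    ta = bump(0.15, 0.10, 0.45) + bump(0.60, 0.10, 0.45))
  lapply(shapes, function(mu) {
    noise <- as.numeric(stats::filter(rnorm(n, 0, 0.02), rep(1 / 7, 7),
                                      circular = TRUE))
    mean_v <- pmin(1, pmax(0, mu + noise))
    data.frame(time_norm = tt, mean = mean_v,
               lo = pmax(0, mean_v - band), hi = pmin(1, mean_v + band))
  })
}
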