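## Reflex controller: parameter layout, pack/unpack, construction, and
## R-level mirrors of the control laws for unit testing and documentation.
## The rollout-time evaluation lives in the engine; both implementations
## follow the same written law.

VESTIB_GROUPS <- c("ilpso", "gmax", "adm", "ham", "sol", "ta")

GAIT_PARAM_NAMES <- c(
  "C_SOL", "G_SOL_F", "C_GAS", "G_GAS_F", "C_GAS_PUSH",
  "C_TA", "G_TA_L", "LO_TA_G", "G_TA_FSOL",
  "C_VAS_G", "G_VAS_F", "S_VAS_LO", "C_VAS_LD", "K_KO",
  "C_GMAX_G", "G_GMAX_P", "G_GMAX_V", "C_GMAX_SW", "C_GMAX_LD",
  "C_ADM_G",
  "C_HAM_G", "G_HAM_P", "G_HAM_V", "G_HAM_SWF", "G_HAM_SWL",
  "LO_HAM_SW", "C_HAM_LD",
  "C_ILP_ST", "G_ILP_P", "G_ILP_V", "C_ILP_PUSH", "C_ILP_LF",
  "C_ILP_SW", "G_ILP_L", "LO_ILP",
  "C_BFSH_LF", "C_RF_ST", "C_RF_SW",
  "THETA0_G", "HIP_SW_THR",
  "TR_L_Q0", "TR_L_KP", "TR_L_KV", "TR_T_Q0", "TR_T_KP", "TR_T_KV")

# initial values for the two standing states and the gait block; the
# starting point of every optimization chain
stand_init <- function(state) {
  g <- MUSCLE_GROUPS
  z <- setNames(numeric(10), g)
  if (state == 1) {
    KC <- z; KC[c("ilpso", "ta")] <- 0.20
    KC[c("rf", "vas")] <- 0.05; KC[c("gmax", "adm", "ham", "bfsh",
                                     "gas", "sol")] <- 0.02
    KP <- c(ilpso = 0, gmax = 0.5, adm = 0.3, ham = 0.5, sol = 0, ta = 0)
    KV <- c(ilpso = 0, gmax = 0.1, adm = 0.1, ham = 0.1, sol = 0, ta = 0)
    list(KC = KC, KL = z, LO = z + 1, KFp = z, KFm = z, KP = KP, KV = KV,
         theta0 = 0.35,
         trunk = c(lum_q0 = 0.45, lum_kp = 180, lum_kv = 12,
                   th_q0 = 0.15, th_kp = 120, th_kv = 8))
  } else {
    KC <- z
    KC[c("ilpso", "bfsh")] <- 0.02
    KC["gmax"] <- 0.30; KC["adm"] <- 0.15; KC["rf"] <- 0.10
    KC["vas"] <- 0.45; KC["ham"] <- 0.10; KC["gas"] <- 0.05
    KC["sol"] <- 0.10; KC["ta"] <- 0.10
    KFp <- z; KFp["vas"] <- 0.3; KFp["sol"] <- 0.3; KFp["gas"] <- 0.1
    KP <- c(ilpso = -1.0, gmax = 1.5, adm = 0.8, ham = 1.0,
            sol = 1.5, ta = -1.5)
    KV <- c(ilpso = -0.2, gmax = 0.3, adm = 0.15, ham = 0.2,
            sol = 0.3, ta = -0.3)
    list(KC = KC, KL = z, LO = z + 1, KFp = KFp, KFm = z, KP = KP, KV = KV,
         theta0 = 0.10,
         trunk = c(lum_q0 = 0.10, lum_kp = 220, lum_kv = 15,
                   th_q0 = 0.05, th_kp = 140, th_kv = 10))
  }
}

gait_init <- function() {
  c(C_SOL = 0.02, G_SOL_F = 1.0, C_GAS = 0.02, G_GAS_F = 1.0,
    C_GAS_PUSH = 0.20, C_TA = 0.05, G_TA_L = 1.5, LO_TA_G = 1.0,
    G_TA_FSOL = 0.4, C_VAS_G = 0.08, G_VAS_F = 1.0, S_VAS_LO = 0.3,
    C_VAS_LD = 0.15, K_KO = 2, C_GMAX_G = 0.05, G_GMAX_P = 1.5,
    G_GMAX_V = 0.3, C_GMAX_SW = 0.02, C_GMAX_LD = 0.10, C_ADM_G = 0.03,
    C_HAM_G = 0.04, G_HAM_P = 1.0, G_HAM_V = 0.2, G_HAM_SWF = 0.3,
    G_HAM_SWL = 1.0, LO_HAM_SW = 0.95, C_HAM_LD = 0.10, C_ILP_ST = 0.02,
    G_ILP_P = 1.0, G_ILP_V = 0.2, C_ILP_PUSH = 0.15, C_ILP_LF = 0.35,
    C_ILP_SW = 0.20, G_ILP_L = 1.0, LO_ILP = 0.90, C_BFSH_LF = 0.25,
    C_RF_ST = 0.02, C_RF_SW = 0.05, THETA0_G = 0.08, HIP_SW_THR = 0.50,
    TR_L_Q0 = 0.10, TR_L_KP = 150, TR_L_KV = 10, TR_T_Q0 = 0.05,
    TR_T_KP = 100, TR_T_KV = 8)
}

gait_bounds <- function(name) {
  if (grepl("^C_", name)) return(c(0, 1))
  if (grepl("^G_.*_(P)$", name)) return(c(-5, 5))
  if (grepl("^G_.*_(V)$", name)) return(c(-2, 2))
  if (grepl("^G_", name)) return(c(0, 5))
  if (grepl("^LO_", name)) return(c(0.5, 1.5))
  switch(name,
         S_VAS_LO = c(0, 1), K_KO = c(0, 10), THETA0_G = c(-0.3, 0.5),
         HIP_SW_THR = c(0, 1.2),
         TR_L_Q0 = c(0, 0.8727), TR_T_Q0 = c(-0.2618, 0.2618),
         TR_L_KP = c(0, 500), TR_T_KP = c(0, 500),
         TR_L_KV = c(0, 50), TR_T_KV = c(0, 50),
         stop("unknown gait parameter ", name))
}

#' Controller parameter layout
#'
#' The canonical flat ordering of every optimizable controller scalar with
#' per-entry bounds, initial value and initial search standard deviation
#' (10% of the box width). Standing-state gains are shared between the left
#' and right leg; gait gains are shared and mirrored.
#'
#' @return data.frame with columns `name`, `block`, `lo`, `hi`, `init`,
#'   `init_std`.
#' @export
controller_layout <- function() {
  rows <- list()
  add <- function(name, block, lo, hi, init)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, block = block, lo = lo, hi = hi, init = init,
      stringsAsFactors = FALSE)
  for (s in 1:2) {
    st <- stand_init(s)
    pre <- paste0("st", s, "_")
    for (g in MUSCLE_GROUPS) {
      add(paste0(pre, "KC_", g), paste0("stand", s), 0, 1, st$KC[[g]])
      add(paste0(pre, "KL_", g), paste0("stand", s), 0, 5, st$KL[[g]])
      add(paste0(pre, "LO_", g), paste0("stand", s), 0.5, 1.5, st$LO[[g]])
      add(paste0(pre, "KFp_", g), paste0("stand", s), 0, 5, st$KFp[[g]])
      add(paste0(pre, "KFm_", g), paste0("stand", s), 0, 5, st$KFm[[g]])
    }
    for (g in VESTIB_GROUPS) {
      add(paste0(pre, "KP_", g), paste0("stand", s), -5, 5, st$KP[[g]])
      add(paste0(pre, "KV_", g), paste0("stand", s), -2, 2, st$KV[[g]])
    }
    add(paste0(pre, "theta0"), paste0("stand", s), -0.5, 1.0, st$theta0)
    tb <- st$trunk
    add(paste0(pre, "trunk_lum_q0"), paste0("stand", s), 0, 0.8727,
        tb[["lum_q0"]])
    add(paste0(pre, "trunk_lum_kp"), paste0("stand", s), 0, 500,
        tb[["lum_kp"]])
    add(paste0(pre, "trunk_lum_kv"), paste0("stand", s), 0, 50,
        tb[["lum_kv"]])
    add(paste0(pre, "trunk_th_q0"), paste0("stand", s), -0.2618, 0.2618,
        tb[["th_q0"]])
    add(paste0(pre, "trunk_th_kp"), paste0("stand", s), 0, 500,
        tb[["th_kp"]])
    add(paste0(pre, "trunk_th_kv"), paste0("stand", s), 0, 50,
        tb[["th_kv"]])
  }
  add("sched_t_state2", "schedule", 0.10, 1.0, 0.40)
  add("sched_t_gait", "schedule", 0.50, 2.5, 1.30)
  add("sched_stance_thr", "schedule", 0.05, 0.6, 0.25)
  gi <- gait_init()
  for (nm in GAIT_PARAM_NAMES) {
    b <- gait_bounds(nm)
    add(paste0("gait_", nm), "gait", b[1], b[2], gi[[nm]])
  }
  out <- do.call(rbind, rows)
  out$init_std <- 0.1 * (out$hi - out$lo)
  out
}

#' Default controller parameter vector
#'
#' @param layout layout table from [controller_layout()].
#' @return named numeric vector of initial values (the neutral optimization
#'   starting point).
#' @export
default_controller_params <- function(layout = controller_layout()) {
  setNames(layout$init, layout$name)
}

#' Unpack a flat parameter vector into the structured controller form
#'
#' Inverse of [pack_params()]; the round-trip is lossless.
#'
#' @param x named numeric vector following [controller_layout()] order.
#' @param layout layout table.
#' @return nested list with `stand` (two states), `schedule` and `gait`.
#' @export
unpack_params <- function(x, layout = controller_layout()) {
  if (length(x) != nrow(layout))
    stop(sprintf("parameter vector length %d does not match layout %d (first expected name: %s)",
                 length(x), nrow(layout), layout$name[1]))
  if (is.null(names(x))) names(x) <- layout$name
  stand <- lapply(1:2, function(s) {
    pre <- paste0("st", s, "_")
    pick <- function(field, groups = MUSCLE_GROUPS) {
      v <- setNames(numeric(length(groups)), groups)
      for (g in groups) {
        key <- paste0(pre, field, "_", g)
        if (key %in% names(x)) v[g] <- x[[key]]
      }
      v
    }
    KP <- setNames(numeric(10), MUSCLE_GROUPS)
    KV <- KP
    KP[VESTIB_GROUPS] <- pick("KP", VESTIB_GROUPS)
    KV[VESTIB_GROUPS] <- pick("KV", VESTIB_GROUPS)
    list(KC = pick("KC"), KL = pick("KL"), LO = pick("LO"),
         KFp = pick("KFp"), KFm = pick("KFm"), KP = KP, KV = KV,
         theta0 = x[[paste0(pre, "theta0")]],
         trunk = c(x[[paste0(pre, "trunk_lum_q0")]],
                   x[[paste0(pre, "trunk_lum_kp")]],
                   x[[paste0(pre, "trunk_lum_kv")]],
                   x[[paste0(pre, "trunk_th_q0")]],
                   x[[paste0(pre, "trunk_th_kp")]],
                   x[[paste0(pre, "trunk_th_kv")]]))
  })
  gait <- setNames(vapply(GAIT_PARAM_NAMES, function(nm)
    x[[paste0("gait_", nm)]], 0), GAIT_PARAM_NAMES)
  list(stand = stand,
       schedule = list(t_state2 = x[["sched_t_state2"]],
                       t_gait = x[["sched_t_gait"]],
                       stance_thr = x[["sched_stance_thr"]]),
       gait = gait)
}

#' Pack the structured controller form into a flat parameter vector
#'
#' @param structured nested list as produced by [unpack_params()].
#' @param layout layout table.
#' @return named numeric vector in canonical order.
#' @export
pack_params <- function(structured, layout = controller_layout()) {
  x <- setNames(numeric(nrow(layout)), layout$name)
  for (s in 1:2) {
    st <- structured$stand[[s]]
    pre <- paste0("st", s, "_")
    for (g in MUSCLE_GROUPS) {
      x[paste0(pre, "KC_", g)] <- st$KC[[g]]
      x[paste0(pre, "KL_", g)] <- st$KL[[g]]
      x[paste0(pre, "LO_", g)] <- st$LO[[g]]
      x[paste0(pre, "KFp_", g)] <- st$KFp[[g]]
      x[paste0(pre, "KFm_", g)] <- st$KFm[[g]]
    }
    for (g in VESTIB_GROUPS) {
      x[paste0(pre, "KP_", g)] <- st$KP[[g]]
      x[paste0(pre, "KV_", g)] <- st$KV[[g]]
    }
    x[paste0(pre, "theta0")] <- st$theta0
    x[paste0(pre, c("trunk_lum_q0", "trunk_lum_kp", "trunk_lum_kv",
                    "trunk_th_q0", "trunk_th_kp", "trunk_th_kv"))] <-
      st$trunk
  }
  x["sched_t_state2"] <- structured$schedule$t_state2
  x["sched_t_gait"] <- structured$schedule$t_gait
  x["sched_stance_thr"] <- structured$schedule$stance_thr
  x[paste0("gait_", GAIT_PARAM_NAMES)] <- structured$gait[GAIT_PARAM_NAMES]
  x
}

#' Construct a reflex sit-to-walk controller
#'
#' @param params named parameter vector (see [controller_layout()]); default
#'   is the neutral starting point.
#' @param gait whether the gait block is active after `t_gait`; with
#'   `FALSE`, the stand-2 state runs for the whole rollout.
#' @return object of class `stw_controller`.
#' @export
reflex_controller <- function(params = default_controller_params(),
                              gait = TRUE) {
  structured <- unpack_params(params)
  if (structured$schedule$t_gait <= structured$schedule$t_state2)
    stop("validation error: t_gait must exceed t_state2")
  structure(list(kind = "reflex", params = params,
                 structured = structured, gait = gait),
            class = "stw_controller")
}

#' Constant-excitation controller (testing and passive studies)
#'
#' @param u per-muscle excitation vector in [0, 1].
#' @return object of class `stw_controller`.
#' @export
constant_controller <- function(u) {
  stopifnot(all(u >= 0), all(u <= 1))
  structure(list(kind = "constant", u = u), class = "stw_controller")
}

# Translate a controller object into the list the engine parses
build_controller_list <- function(controller, model) {
  if (is.null(controller)) return(list(kind = 0L))
  if (controller$kind == "constant")
    return(list(kind = 1L, u = as.numeric(controller$u)))
  st <- controller$structured
  stand <- lapply(st$stand, function(s)
    list(KC = unname(s$KC), KL = unname(s$KL), LO = unname(s$LO),
         KFp = unname(s$KFp), KFm = unname(s$KFm), KP = unname(s$KP),
         KV = unname(s$KV), theta0 = s$theta0, trunk = unname(s$trunk)))
  t_gait <- if (controller$gait) st$schedule$t_gait else 1e9
  list(kind = 2L, t_state2 = st$schedule$t_state2, t_gait = t_gait,
       stance_thr = st$schedule$stance_thr, stand = stand,
       has_gait = TRUE, gait = st$gait)
}

#' Delayed signal lookup
#'
#' Returns the value of a sampled signal `delay` seconds before `t`,
#' linearly interpolated between samples and zero-padded before the first
#' sample (signals are taken to be zero before recording starts).
#'
#' @param t query time, s.
#' @param times sample times (increasing), s.
#' @param values sample values.
#' @param delay neural latency, s (>= 0).
#' @return interpolated delayed value.
#' @export
delayed_signal <- function(t, times, values, delay) {
  stopifnot(delay >= 0)
  tq <- t - delay
  if (tq < times[1]) return(0)
  approx(times, values, xout = tq, rule = 2)$y
}

#' Controller mode at a given time
#'
#' One-way schedule: standing state 1 before `t_state2`, standing state 2
#' from `t_state2` (boundary included) to `t_gait`, gait afterwards.
#'
#' @param t time, s.
#' @param schedule list with `t_state2` and `t_gait`.
#' @return one of `"stand1"`, `"stand2"`, `"gait"`.
#' @export
advance_state_machine <- function(t, schedule) {
  if (schedule$t_gait <= schedule$t_state2)
    stop("validation error: t_gait must exceed t_state2")
  if (t < schedule$t_state2) "stand1"
  else if (t < schedule$t_gait) "stand2"
  else "gait"
}

#' Standing-state reflex law (reference implementation)
#'
#' Computes per-muscle excitations from delayed signals under one standing
#' state's gains:
#' `u = clamp01(KC + KL max(0, L - lo) + KFp F - KFm F_antagonist
#'  + Kp (theta - theta0) + Kv thetad)`, lengths normalized by optimal
#' fiber length and forces by maximum isometric force. This mirrors the
#' engine's in-loop evaluation and is used for direct unit checks.
#'
#' @param signals data.frame with one row per muscle and columns `group`,
#'   `lt` (delayed normalized length), `ft` (delayed normalized force),
#'   `ft_antag` (delayed antagonist normalized force).
#' @param gains one standing state's structured gain list.
#' @param theta,thetad delayed pelvis tilt and tilt velocity, rad and rad/s.
#' @return excitation vector in [0, 1].
#' @export
stand_excitations <- function(signals, gains, theta = 0, thetad = 0) {
  u <- vapply(seq_len(nrow(signals)), function(i) {
    g <- signals$group[i]
    val <- gains$KC[[g]] +
      gains$KL[[g]] * max(0, signals$lt[i] - gains$LO[[g]]) +
      gains$KFp[[g]] * signals$ft[i] -
      gains$KFm[[g]] * signals$ft_antag[i] +
      gains$KP[[g]] * (theta - gains$theta0) +
      gains$KV[[g]] * thetad
    min(1, max(0, val))
  }, 0)
  setNames(u, signals$group)
}

#' Gait reflex law (reference implementation)
#'
#' Phase-gated reflex excitations for one leg's muscles given the leg's
#' machine state. Mirrors the engine's gait controller on a signal
#' snapshot; used for symmetry and gating unit checks.
#'
#' @param signals data.frame with columns `group`, `lt`, `ft`, plus
#'   `ft_sol` (same-leg soleus normalized force).
#' @param gait named gait parameter vector.
#' @param leg_state one of `"early_stance"`, `"late_stance"`, `"liftoff"`,
#'   `"swing"`, `"landing"`.
#' @param theta,thetad delayed pelvis tilt and velocity.
#' @param q_knee current knee angle (rad, flexion negative).
#' @return excitation vector in [0, 1].
#' @export
gait_excitations <- function(signals, gait, leg_state, theta = 0,
                             thetad = 0, q_knee = -0.3) {
  P <- function(nm) gait[[nm]]
  dth <- theta - P("THETA0_G")
  stance <- leg_state %in% c("early_stance", "late_stance", "landing")
  u <- vapply(seq_len(nrow(signals)), function(i) {
    g <- signals$group[i]
    val <- 0.01
    if (g == "sol" && stance) val <- P("C_SOL") + P("G_SOL_F") * signals$ft[i]
    if (g == "gas") {
      if (stance) val <- P("C_GAS") + P("G_GAS_F") * signals$ft[i]
      if (leg_state %in% c("late_stance", "liftoff"))
        val <- val + P("C_GAS_PUSH")
    }
    if (g == "ta") {
      val <- P("C_TA") + P("G_TA_L") * max(0, signals$lt[i] - P("LO_TA_G"))
      if (stance) val <- val - P("G_TA_FSOL") * signals$ft_sol[i]
    }
    if (g == "vas") {
      if (leg_state %in% c("early_stance", "landing"))
        val <- P("C_VAS_G") + P("G_VAS_F") * signals$ft[i]
      if (leg_state == "late_stance")
        val <- P("S_VAS_LO") * (P("C_VAS_G") + P("G_VAS_F") * signals$ft[i])
      if (leg_state == "landing") val <- val + P("C_VAS_LD")
      val <- val - P("K_KO") * max(0, q_knee - (-0.06))
    }
    if (g == "gmax") {
      if (stance) val <- P("C_GMAX_G") +
          max(0, P("G_GMAX_P") * dth + P("G_GMAX_V") * thetad)
      if (leg_state == "swing") val <- P("C_GMAX_SW")
      if (leg_state == "landing") val <- val + P("C_GMAX_LD")
    }
    if (g == "adm" && stance) val <- P("C_ADM_G") +
        0.5 * max(0, P("G_GMAX_P") * dth + P("G_GMAX_V") * thetad)
    if (g == "ham") {
      if (stance) val <- P("C_HAM_G") +
          max(0, P("G_HAM_P") * dth + P("G_HAM_V") * thetad)
      if (leg_state == "swing")
        val <- P("G_HAM_SWF") * signals$ft[i] +
          P("G_HAM_SWL") * max(0, signals$lt[i] - P("LO_HAM_SW"))
      if (leg_state == "landing") val <- val + P("C_HAM_LD")
    }
    if (g == "ilpso") {
      if (stance) val <- P("C_ILP_ST") +
          max(0, -P("G_ILP_P") * dth - P("G_ILP_V") * thetad)
      if (leg_state == "late_stance") val <- val + P("C_ILP_PUSH")
      if (leg_state == "liftoff") val <- P("C_ILP_LF")
      if (leg_state == "swing")
        val <- P("C_ILP_SW") +
          P("G_ILP_L") * max(0, signals$lt[i] - P("LO_ILP"))
    }
    if (g == "bfsh" && leg_state == "liftoff") val <- P("C_BFSH_LF")
    if (g == "rf") {
      if (stance) val <- P("C_RF_ST")
      if (leg_state == "swing") val <- P("C_RF_SW")
    }
    min(1, max(0, val))
  }, 0)
  setNames(u, signals$group)
}

#' Write controller parameters to a plain-text file
#'
#' One scalar per line (`name value init_std min max`), diffable and usable
#' as a warm start for later optimizations.
#'
#' @param params named parameter vector.
#' @param path output file.
#' @param layout layout table (for bounds and stds).
#' @export
write_params <- function(params, path, layout = controller_layout()) {
  stopifnot(length(params) == nrow(layout))
  df <- data.frame(name = layout$name, value = unname(params[layout$name]),
                   init_std = layout$init_std, min = layout$lo,
                   max = layout$hi)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read controller parameters from a plain-text file
#'
#' @param path file written by [write_params()].
#' @return named numeric parameter vector.
#' @export
read_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(df$value, df$name)
}
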