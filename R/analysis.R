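## Movement measures and file writers: trunk flexion, movement events
## (seat-off, toe-offs, heel strikes), timing, peak loads and activations;
## trajectory CSV / OpenSim storage / JSON / plot outputs.

#' Trunk flexion of a pose
#'
#' Angle of the trunk against the global vertical, computed as the sum of
#' pelvis tilt, lumbar and thoracic angles (all forward-positive in this
#' package), reported in degrees with forward lean positive.
#'
#' @param pelvis_tilt,lumbar,thoracic angles in rad (vectors allowed).
#' @return trunk flexion in degrees.
#' @export
trunk_flexion <- function(pelvis_tilt, lumbar, thoracic) {
  (pelvis_tilt + lumbar + thoracic) * 180 / pi
}

# start times of runs where `x < eps` (below = TRUE) or `x > eps` lasting at
# least `debounce` seconds
sustained_crossings <- function(t, x, eps, debounce, below = TRUE) {
  cond <- if (below) x < eps else x > eps
  if (!any(cond)) return(numeric(0))
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  keep <- r$values & (r$lengths * dt >= debounce)
  t[starts[keep]]
}

#' Detect movement events in a trajectory
#'
#' Seat-off is the first time the total chair load falls below `eps` and
#' stays below for at least `debounce`; toe-offs and heel strikes are the
#' corresponding debounced crossings of each foot's ground reaction force;
#' movement onset is the first sample with appreciable joint motion.
#' Compliant contact never reaches exactly zero numerically, hence the
#' 5 N / 50 ms rule. Missing events are absent entries, not errors.
#'
#' @param traj an `stw_trajectory`.
#' @param eps force threshold, N.
#' @param debounce minimum sustained duration, s.
#' @return list of class `stw_events` with `seat_off`, `seat_unload_init`,
#'   `toe_offs` (merged, sorted), `toe_offs_r/l`, `heel_strikes` (merged),
#'   `heel_strikes_r/l`, `gait_start` (first heel strike after
#'   seat-off), `movement_onset`.
#' @export
detect_events <- function(traj, eps = 5, debounce = 0.05) {
  t <- traj$t
  ev <- list()
  chair <- traj$chair_fy
  so <- sustained_crossings(t, chair, eps, debounce, below = TRUE)
  # seat-off requires prior seated contact
  so <- so[so > 0 | chair[1] < eps]
  ev$seat_off <- if (chair[1] > eps && length(so)) so[1] else NULL
  settled <- median(chair[t <= t[1] + 0.1])
  ui <- sustained_crossings(t, chair, 0.95 * settled, debounce, below = TRUE)
  ev$seat_unload_init <- if (settled > eps && length(ui)) ui[1] else NULL
  for (side in c("r", "l")) {
    g <- traj[[paste0("grf_", side, "_fy")]]
    to <- sustained_crossings(t, g, eps, debounce, below = TRUE)
    to <- to[to > t[1]]
    hs <- sustained_crossings(t, g, eps, debounce, below = FALSE)
    hs <- if (length(to)) hs[hs > to[1]] else numeric(0)
    ev[[paste0("toe_offs_", side)]] <- to
    ev[[paste0("heel_strikes_", side)]] <- hs
  }
  ev$toe_offs <- sort(c(ev$toe_offs_r, ev$toe_offs_l))
  ev$heel_strikes <- sort(c(ev$heel_strikes_r, ev$heel_strikes_l))
  # gait begins at the first heel strike after seat-off; contact-settling
  # transients before seat-off cannot open the gait phase
  gs <- ev$heel_strikes
  if (!is.null(ev$seat_off)) gs <- gs[gs > ev$seat_off]
  if (length(gs)) ev$gait_start <- gs[1]
  qd <- as.matrix(traj[paste0("d_", c("pelvis_tilt", "hip_r", "hip_l",
                                      "lumbar"))])
  mv <- which(sqrt(rowSums(qd^2)) > 0.1)
  ev$movement_onset <- if (length(mv)) t[mv[1]] else t[1]
  class(ev) <- "stw_events"
  ev
}

#' Summary measures of a sit-to-walk trajectory
#'
#' Trunk flexion at seat-off, maximum trunk flexion over the
#' onset-to-seat-unloading window, time from movement onset to the first
#' heel strike of the stepping leg, peak joint loads (BW) and peak muscle
#' activations. Missing events yield `NA` entries rather than errors.
#'
#' @param traj an `stw_trajectory`.
#' @param events precomputed [detect_events()] result (optional).
#' @return list of class `stw_metrics`.
#' @export
movement_metrics <- function(traj, events = NULL) {
  if (is.null(events)) events <- detect_events(traj)
  tf <- trunk_flexion(traj$pelvis_tilt, traj$lumbar, traj$thoracic)
  at_time <- function(x, tt) if (is.null(tt)) NA_real_ else
    approx(traj$t, x, xout = tt, rule = 2)$y
  win_hi <- if (!is.null(events$seat_unload_init)) events$seat_unload_init
    else if (!is.null(events$seat_off)) events$seat_off
    else traj$t[nrow(traj)]
  win <- traj$t >= events$movement_onset & traj$t <= win_hi
  loads <- list()
  for (j in c("hip", "knee", "ankle")) for (s in c("r", "l"))
    loads[[paste0(j, "_", s)]] <- max(joint_load(traj, j, s))
  acols <- grep("^a_", names(traj), value = TRUE)
  peak_act <- vapply(traj[acols], max, 0)
  names(peak_act) <- sub("^a_", "", names(peak_act))
  hs_l <- events$heel_strikes_l
  if (!is.null(events$seat_off)) hs_l <- hs_l[hs_l > events$seat_off]
  structure(list(
    trunk_flexion_at_seat_off = at_time(tf, events$seat_off),
    max_trunk_flexion = if (any(win)) max(tf[win]) else NA_real_,
    trunk_flexion_raw_sum_deg = max(tf),
    time_to_first_heel_strike = if (length(hs_l))
      hs_l[1] - events$movement_onset else NA_real_,
    peak_loads_bw = unlist(loads),
    peak_activations = peak_act,
    events = events), class = "stw_metrics")
}

#' @export
print.stw_metrics <- function(x, ...) {
  cat(sprintf("<metrics> trunk flexion at seat-off: %.1f deg, max: %.1f deg\n",
              x$trunk_flexion_at_seat_off, x$max_trunk_flexion))
  cat(sprintf("  time to first heel strike (stepping leg): %.2f s\n",
              x$time_to_first_heel_strike))
  cat("  peak loads [BW]:",
      paste(names(x$peak_loads_bw),
            sprintf("%.2f", x$peak_loads_bw), collapse = ", "), "\n")
  invisible(x)
}

#' Write trajectory and reports to a directory
#'
#' Writes the trajectory as CSV (stable column order, one row per output
#' sample) and as an OpenSim storage (.sto) coordinate file for external
#' visualization, plus metrics/objective JSON and diagnostic PNG panels.
#'
#' @param traj an `stw_trajectory`.
#' @param dir output directory (created if needed).
#' @param metrics optional [movement_metrics()] result.
#' @param objective optional [evaluate_objective()] report.
#' @param prefix file-name prefix.
#' @param plots whether to render PNG panels.
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(traj, dir, metrics = NULL, objective = NULL,
                          prefix = "rollout", plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fcsv <- file.path(dir, paste0(prefix, "_trajectory.csv"))
  write.csv(as.data.frame(traj), fcsv, row.names = FALSE)
  files <- c(files, fcsv)
  fsto <- file.path(dir, paste0(prefix, ".sto"))
  write_sto(traj, fsto)
  files <- c(files, fsto)
  if (!is.null(metrics)) {
    fj <- file.path(dir, paste0(prefix, "_metrics.json"))
    m <- metrics; m$events <- lapply(unclass(m$events), as.numeric)
    jsonlite::write_json(unclass(m), fj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, fj)
  }
  if (!is.null(objective)) {
    fo <- file.path(dir, paste0(prefix, "_objective.json"))
    o <- unclass(objective); o$events <- NULL
    jsonlite::write_json(o, fo, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, fo)
  }
  if (plots) {
    fp <- file.path(dir, paste0(prefix, "_panels.png"))
    grDevices::png(fp, width = 1400, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    tf <- trunk_flexion(traj$pelvis_tilt, traj$lumbar, traj$thoracic)
    graphics::plot(traj$t, tf, type = "l", xlab = "time [s]",
                   ylab = "trunk flexion [deg]", main = "Trunk flexion")
    graphics::plot(traj$t, traj$chair_fy, type = "l", xlab = "time [s]",
                   ylab = "force [N]", main = "Chair and ground loads")
    graphics::lines(traj$t, traj$grf_r_fy, col = "red")
    graphics::lines(traj$t, traj$grf_l_fy, col = "blue")
    graphics::legend("topright", c("chair", "GRF right", "GRF left"),
                     col = c("black", "red", "blue"), lty = 1, bty = "n")
    bw <- attr(traj, "model_mass") * attr(traj, "gravity")
    graphics::plot(traj$t, traj$load_knee_l / bw, type = "l", col = "blue",
                   xlab = "time [s]", ylab = "knee load [BW]",
                   main = "Knee loads",
                   ylim = c(0, max(traj$load_knee_l, traj$load_knee_r) / bw))
    graphics::lines(traj$t, traj$load_knee_r / bw, col = "red")
    graphics::plot(traj$t, traj$a_vas_l, type = "l", col = "blue",
                   ylim = c(0, 1), xlab = "time [s]", ylab = "activation",
                   main = "VAS / HAM activation (stepping leg)")
    graphics::lines(traj$t, traj$a_ham_l, col = "purple")
    files <- c(files, fp)
  }
  invisible(files)
}

#' Write an OpenSim storage (.sto) motion file
#'
#' Text storage format with the coordinate columns of the trajectory, so
#' the motion can be animated in external viewers against a matching model.
#' Angles are written in radians (`inDegrees=no`).
#'
#' @param traj an `stw_trajectory`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sto <- function(traj, path) {
  qcols <- intersect(DOF_NAMES, names(traj))
  dat <- cbind(time = traj$t, traj[qcols])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("sit_to_walk_motion", "version=1",
               sprintf("nRows=%d", nrow(dat)),
               sprintf("nColumns=%d", ncol(dat)),
               "inDegrees=no", "endheader",
               paste(names(dat), collapse = "\t")), con)
  utils::write.table(dat, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read back a trajectory CSV written by [write_outputs()]
#'
#' @param path CSV file.
#' @param model_mass,gravity attributes to restore (defaults match the
#'   default model).
#' @return an `stw_trajectory`.
#' @export
read_trajectory <- function(path, model_mass = 75, gravity = 9.81) {
  traj <- read.csv(path)
  attr(traj, "status") <- "ok"
  attr(traj, "model_mass") <- model_mass
  attr(traj, "gravity") <- gravity
  class(traj) <- c("stw_trajectory", "data.frame")
  traj
}
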