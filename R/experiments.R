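## Condition grid and study orchestration: neutral condition, bilateral
## vasti-weakness sweep (warm-started from mild to severe), and the
## pain-avoidance sweep of stepping-knee load thresholds.

#' Define an experimental condition
#'
#' @param kind `"neutral"`, `"weakness"` (bilateral VAS maximum-isometric-
#'   force scaling) or `"pain"` (stepping-knee peak-load threshold).
#' @param vas_scale fraction of the nominal VAS strength (weakness only),
#'   e.g. 0.8 for a 20% reduction.
#' @param pain_threshold_bw knee-load threshold in body weights (pain
#'   only), one of the 4/3/2 sweep by default.
#' @param pain_leg which leg's knee carries the cost; the stepping leg
#'   (left) unless studying the mirrored variant.
#' @return list of class `stw_condition`.
#' @export
condition_spec <- function(kind = c("neutral", "weakness", "pain"),
                           vas_scale = NULL, pain_threshold_bw = NULL,
                           pain_leg = "l") {
  kind <- match.arg(kind)
  if (kind == "weakness") {
    stopifnot(!is.null(vas_scale))
    if (vas_scale <= 0) stop("vas_scale must be positive")
    if (!is.null(pain_threshold_bw))
      stop("weakness conditions do not take a pain threshold")
  }
  if (kind == "pain") {
    stopifnot(!is.null(pain_threshold_bw), pain_threshold_bw > 0)
    if (!is.null(vas_scale)) stop("pain conditions do not scale muscles")
  }
  if (kind == "neutral" && (!is.null(vas_scale) ||
                            !is.null(pain_threshold_bw)))
    stop("neutral conditions carry no modifiers")
  structure(list(kind = kind, vas_scale = vas_scale,
                 pain_threshold_bw = pain_threshold_bw,
                 pain_leg = pain_leg,
                 id = switch(kind, neutral = "neutral",
                             weakness = sprintf("weakness_%02.0f",
                                                100 * vas_scale),
                             pain = sprintf("pain_%gbw", pain_threshold_bw))),
            class = "stw_condition")
}

#' The default study grid
#'
#' Neutral, then bilateral VAS weakness at 80/70/60/50/40% of nominal
#' strength, then stepping-knee load thresholds of 4/3/2 BW.
#'
#' @param vas_scales weakness sweep (ordered mild to severe).
#' @param pain_thresholds_bw pain sweep (ordered lenient to strict).
#' @return list of `stw_condition`s.
#' @export
study_grid <- function(vas_scales = c(0.8, 0.7, 0.6, 0.5, 0.4),
                       pain_thresholds_bw = c(4, 3, 2)) {
  c(list(condition_spec("neutral")),
    lapply(vas_scales, function(s) condition_spec("weakness", vas_scale = s)),
    lapply(pain_thresholds_bw,
           function(p) condition_spec("pain", pain_threshold_bw = p)))
}

#' Apply a condition to model and objective
#'
#' Weakness scales the left and right VAS maximum isometric force (their
#' metabolic muscle mass scales with it through the mass formula) and
#' leaves the objective untouched; pain leaves the model untouched and adds
#' the knee-load cost to the objective; neutral is the identity.
#'
#' @param model the nominal `stw_model`.
#' @param spec an [condition_spec()].
#' @param objective the nominal [objective_config()].
#' @return list with modified `model` and `objective`.
#' @export
apply_condition <- function(model, spec, objective = objective_config()) {
  stopifnot(inherits(spec, "stw_condition"))
  if (spec$kind == "weakness") {
    i <- model$muscles$group == "vas"
    model$muscles$fmax[i] <- model$muscles$fmax[i] * spec$vas_scale
  } else if (spec$kind == "pain") {
    objective$pain_threshold_bw <- spec$pain_threshold_bw
    objective$pain_leg <- spec$pain_leg
  }
  list(model = model, objective = objective)
}

# stable short hash for provenance records (content fingerprint only)
param_hash <- function(x) {
  b <- as.integer(charToRaw(paste(format(x, digits = 12), collapse = ",")))
  sprintf("%08x", sum(b * seq_along(b)) %% .Machine$integer.max)
}

#' Build the rollout cost function for one condition
#'
#' @param model nominal model.
#' @param spec condition.
#' @param preset simulation preset from [desk_preset()] (durations, steps).
#' @param objective nominal objective configuration.
#' @return function mapping a named parameter vector to the scalar
#'   objective total.
#' @export
condition_cost <- function(model, spec, preset = desk_preset(),
                           objective = objective_config()) {
  ap <- apply_condition(model, spec, objective)
  state <- seated_state(ap$model)
  function(params) {
    # total cost function: structurally invalid parameter combinations
    # (e.g. a gait handover before the second standing state) are priced
    # at the failure floor instead of raising
    ctrl <- tryCatch(reflex_controller(params), error = function(e) NULL)
    if (is.null(ctrl)) return(ap$objective$failure_cost + 1000)
    traj <- integrate_rollout(ap$model, state, ctrl,
                              duration = preset$duration, dt = preset$dt,
                              out_dt = preset$out_dt)
    evaluate_objective(traj, ap$objective)$J_total
  }
}

#' Run the sit-to-walk study over a condition grid
#'
#' Orchestrates the full experiment: the neutral condition is optimized
#' first (or taken from `base_params` when already solved); the weakness
#' chain is then warm-started condition-to-condition in order of
#' increasing severity, and likewise the pain chain in order of
#' decreasing threshold. Every condition's best controller is re-simulated
#' and analyzed, and a condition whose best rollout never reaches seat-off
#' is flagged `no_solution` ("unable to rise unaided") with its budget
#' recorded.
#'
#' @param model nominal model.
#' @param grid list of conditions from [study_grid()].
#' @param config an [optimization_config()].
#' @param preset simulation preset ([desk_preset()] by default).
#' @param base_params starting parameters for the neutral condition
#'   (defaults to the package's neutral warm start, see
#'   [neutral_warm_start()]).
#' @param objective nominal objective configuration.
#' @param optimize_neutral whether to re-optimize the neutral condition or
#'   evaluate `base_params` as-is.
#' @param out_dir optional directory; each condition's parameters,
#'   trajectory CSV/.sto and reports are written as it finishes.
#' @return list of class `stw_study`, one entry per condition.
#' @export
run_study <- function(model = build_default_model(), grid = study_grid(),
                      config = optimization_config(),
                      preset = desk_preset(),
                      base_params = neutral_warm_start(),
                      objective = objective_config(),
                      optimize_neutral = TRUE, out_dir = NULL) {
  layout <- controller_layout()
  kinds <- vapply(grid, `[[`, "", "kind")
  results <- list()

  analyze <- function(spec, params, opt_res) {
    ap <- apply_condition(model, spec, objective)
    traj <- integrate_rollout(ap$model, seated_state(ap$model),
                              reflex_controller(params),
                              duration = preset$duration, dt = preset$dt,
                              out_dt = preset$out_dt)
    rep <- evaluate_objective(traj, ap$objective)
    ev <- detect_events(traj)
    met <- movement_metrics(traj, ev)
    no_sol <- !identical(attr(traj, "status"), "ok") ||
      is.null(ev$seat_off)
    entry <- list(spec = spec, params = params, opt = opt_res,
                  trajectory = traj, objective = rep, metrics = met,
                  no_solution = no_sol, seed = config$seed,
                  param_hash = param_hash(params),
                  budget = c(generations = config$max_generations,
                             population = config$population_size,
                             restarts = config$n_parallel))
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, spec$id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_params(params, file.path(d, "params.txt"), layout)
      write_outputs(traj, d, met, rep, prefix = spec$id, plots = TRUE)
      jsonlite::write_json(
        list(condition = spec$id, seed = config$seed,
             param_hash = entry$param_hash,
             no_solution = no_sol, budget = as.list(entry$budget)),
        file.path(d, "provenance.json"), auto_unbox = TRUE)
    }
    entry
  }

  run_one <- function(spec, start) {
    cost <- condition_cost(model, spec, preset, objective)
    res <- optimize_controller(cost, start, config, layout = layout,
                               free = preset$free)
    analyze(spec, res$best_params, res)
  }

  # neutral first
  neutral_params <- base_params
  if ("neutral" %in% kinds) {
    spec <- grid[[which(kinds == "neutral")[1]]]
    if (optimize_neutral) {
      entry <- run_one(spec, base_params)
      neutral_params <- entry$params
    } else {
      entry <- analyze(spec, base_params, NULL)
    }
    results[[spec$id]] <- entry
  }
  # weakness chain, mild to severe
  widx <- which(kinds == "weakness")
  if (length(widx)) {
    scales <- vapply(grid[widx], `[[`, 0, "vas_scale")
    start <- neutral_params
    for (i in widx[order(-scales)]) {
      entry <- run_one(grid[[i]], start)
      results[[grid[[i]]$id]] <- entry
      if (!entry$no_solution) start <- entry$params
    }
  }
  # pain chain, lenient to strict
  pidx <- which(kinds == "pain")
  if (length(pidx)) {
    thr <- vapply(grid[pidx], `[[`, 0, "pain_threshold_bw")
    start <- neutral_params
    for (i in pidx[order(-thr)]) {
      entry <- run_one(grid[[i]], start)
      results[[grid[[i]]$id]] <- entry
      if (!entry$no_solution) start <- entry$params
    }
  }
  structure(results, class = "stw_study")
}

#' Condition summary table of a study
#'
#' @param study an `stw_study`.
#' @return data.frame with one row per condition: trunk flexion at
#'   seat-off, peak loads, timing, feasibility.
#' @export
study_summary <- function(study) {
  do.call(rbind, lapply(study, function(e) {
    m <- e$metrics
    data.frame(
      condition = e$spec$id, kind = e$spec$kind,
      no_solution = e$no_solution,
      J_total = e$objective$J_total,
      trunk_flexion_seat_off = m$trunk_flexion_at_seat_off,
      max_trunk_flexion = m$max_trunk_flexion,
      t_first_heel_strike = m$time_to_first_heel_strike,
      peak_knee_r = m$peak_loads_bw[["knee_r"]],
      peak_knee_l = m$peak_loads_bw[["knee_l"]],
      peak_ankle_l = m$peak_loads_bw[["ankle_l"]],
      peak_vas = max(m$peak_activations[["vas_r"]],
                     m$peak_activations[["vas_l"]]),
      stringsAsFactors = FALSE)
  }))
}
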