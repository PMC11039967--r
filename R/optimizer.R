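## CMA-ES optimization of the controller parameter vector.
##
## Covariance Matrix Adaptation Evolution Strategy in the standard
## (mu/mu_w, lambda) formulation with cumulative step-size adaptation,
## rank-one and rank-mu covariance updates. The search runs in box-
## normalized coordinates (each parameter mapped to [0, 1]) so one step
## scale is meaningful across heterogeneous gains; candidates are projected
## onto the box for evaluation.

#' CMA-ES minimizer
#'
#' @param fn objective function taking a parameter vector (original scale)
#'   and returning a finite scalar cost (failure costs included, never NA).
#' @param x0 starting point.
#' @param lower,upper box bounds (recycled to length of `x0`).
#' @param sigma0 initial step size in normalized coordinates (fraction of
#'   box width).
#' @param popsize candidates per generation (lambda).
#' @param max_gen generation budget.
#' @param seed RNG seed; identical seeds give bit-identical runs.
#' @param stop_fitness stop when the best cost falls below this.
#' @param stagnation_gens stop after this many generations without
#'   improvement of the best cost by more than `stagnation_tol`.
#' @param stagnation_tol see above.
#' @return list with `x_best`, `f_best`, `trace` (data.frame of generation,
#'   best, median, sigma), `n_eval`, `seed`.
#' @export
cma_es <- function(fn, x0, lower, upper, sigma0 = 0.05, popsize = 10,
                   max_gen = 100, seed = 1, stop_fitness = -Inf,
                   stagnation_gens = 200, stagnation_tol = 1e-6) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  width <- upper - lower
  stopifnot(all(width > 0), popsize >= 4)
  to_unit <- function(x) (x - lower) / width
  to_orig <- function(z) lower + pmin(1, pmax(0, z)) * width

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  lambda <- popsize
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- to_unit(x0)
  sigma <- sigma0
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  ps <- numeric(n); pc <- numeric(n)
  eigen_every <- max(1, floor(1 / ((c1 + cmu) * n * 10)))
  f_best <- Inf; x_best <- x0
  last_impr_gen <- 0
  trace <- vector("list", max_gen)
  n_eval <- 0

  for (gen in seq_len(max_gen)) {
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                 # n x lambda
    X <- m + sigma * Y
    fit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      fit[k] <- fn(to_orig(X[, k]))
      n_eval <- n_eval + 1
    }
    ord <- order(fit)
    if (fit[ord[1]] < f_best - stagnation_tol) last_impr_gen <- gen
    if (fit[ord[1]] < f_best) {
      f_best <- fit[ord[1]]
      x_best <- to_orig(X[, ord[1]])
    }
    sel <- ord[seq_len(mu)]
    ybar <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * ybar
    m <- pmin(1.2, pmax(-0.2, m))      # keep the mean near the box
    # step-size path
    Cinvsqrt_y <- B %*% ((1 / D) * crossprod(B, ybar))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsqrt_y)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    # covariance update
    artmp <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)
    if (gen %% eigen_every == 0) {
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
    }
    trace[[gen]] <- data.frame(generation = gen, best = fit[ord[1]],
                               median = median(fit), sigma = sigma,
                               best_ever = f_best)
    if (f_best <= stop_fitness) break
    if (gen - last_impr_gen >= stagnation_gens) break
  }
  list(x_best = x_best, f_best = f_best,
       trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
       n_eval = n_eval, seed = seed)
}

#' Optimization configuration
#'
#' @param population_size lambda per generation.
#' @param max_generations generation budget.
#' @param sigma0 initial normalized step size.
#' @param n_parallel number of independent restarts per condition (the best
#'   is kept); restarts are evaluated sequentially and deterministically.
#' @param seed base seed; restart i uses `seed + i - 1`.
#' @return list of class `stw_opt_config`.
#' @export
optimization_config <- function(population_size = 10, max_generations = 100,
                                sigma0 = 0.05, n_parallel = 3, seed = 1) {
  stopifnot(population_size >= 4)
  structure(list(population_size = population_size,
                 max_generations = max_generations, sigma0 = sigma0,
                 n_parallel = n_parallel, seed = seed),
            class = "stw_opt_config")
}

#' Optimize a cost function over the controller parameter box
#'
#' Runs `n_parallel` independent CMA-ES restarts from the same initial
#' guess (different seeds) and reports the best. Deterministic given the
#' configuration seed.
#'
#' @param cost_fn function(params named vector) -> scalar cost.
#' @param x0 initial parameter vector (named, layout order).
#' @param config an [optimization_config()].
#' @param layout controller layout (bounds).
#' @param free optional character vector of parameter names the optimizer
#'   may vary; the rest stay frozen at `x0` (used by reduced presets that
#'   keep e.g. the gait block fixed). `NULL` frees everything.
#' @return list of class `stw_opt_result` with `best_params`, `best_cost`,
#'   `restarts` (per-restart summaries), `trace` of the winning restart.
#' @export
optimize_controller <- function(cost_fn, x0, config = optimization_config(),
                                layout = controller_layout(), free = NULL) {
  stopifnot(length(x0) == nrow(layout))
  if (config$max_generations == 0) {
    return(structure(list(best_params = x0, best_cost = cost_fn(x0),
                          restarts = NULL, trace = NULL,
                          seed = config$seed), class = "stw_opt_result"))
  }
  if (is.null(free)) free <- layout$name
  sub <- layout[layout$name %in% free, , drop = FALSE]
  full0 <- setNames(unname(x0[layout$name]), layout$name)
  expand <- function(xs) { v <- full0; v[sub$name] <- xs; v }
  runs <- lapply(seq_len(config$n_parallel), function(i) {
    cma_es(function(xs) cost_fn(expand(xs)),
           x0 = unname(full0[sub$name]),
           lower = sub$lo, upper = sub$hi,
           sigma0 = config$sigma0, popsize = config$population_size,
           max_gen = config$max_generations, seed = config$seed + i - 1)
  })
  best <- which.min(vapply(runs, `[[`, 0, "f_best"))
  structure(list(
    best_params = expand(runs[[best]]$x_best),
    best_cost = runs[[best]]$f_best,
    restarts = data.frame(
      restart = seq_along(runs),
      seed = vapply(runs, `[[`, 0, "seed"),
      best = vapply(runs, `[[`, 0, "f_best"),
      n_eval = vapply(runs, `[[`, 0, "n_eval")),
    trace = runs[[best]]$trace, seed = config$seed),
    class = "stw_opt_result")
}

#' Warm-started optimization chain over ordered conditions
#'
#' Conditions are solved in order of increasing severity; each condition's
#' restarts start from the best parameters of the previous condition
#' (condition 1 starts from `base_params`). A condition whose cost never
#' drops below `feasible_cost` is flagged `no_solution`; the chain then
#' continues from the last feasible parameters.
#'
#' @param make_cost function(condition) returning the cost function for
#'   that condition.
#' @param conditions list of condition descriptors (ordered).
#' @param base_params starting parameter vector for the first condition.
#' @param config an [optimization_config()].
#' @param feasible_cost costs at or above this mark a failed condition
#'   (default: the failure floor of the objective).
#' @param layout controller layout.
#' @return list of per-condition `stw_opt_result`s, each with an added
#'   `no_solution` flag and `condition` field.
#' @export
warm_start_chain <- function(make_cost, conditions, base_params,
                             config = optimization_config(),
                             feasible_cost = 1e4,
                             layout = controller_layout()) {
  out <- vector("list", length(conditions))
  start <- base_params
  for (k in seq_along(conditions)) {
    res <- optimize_controller(make_cost(conditions[[k]]), start, config,
                               layout)
    res$condition <- conditions[[k]]
    res$no_solution <- res$best_cost >= feasible_cost
    res$budget <- c(generations = config$max_generations,
                    population = config$population_size,
                    restarts = config$n_parallel)
    out[[k]] <- res
    if (!res$no_solution) start <- res$best_params
  }
  out
}
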