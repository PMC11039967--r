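sphere <- function(x) sum(x^2)

test_that("CMA-ES solves the 10-D sphere to 1e-8 within 300 generations", {
  res <- cma_es(sphere, x0 = rep(0.5, 10), lower = -1, upper = 1,
                sigma0 = 0.3, popsize = 10, max_gen = 300, seed = 4,
                stop_fitness = 1e-9)
  expect_lt(res$f_best, 1e-8)
  expect_lte(max(res$trace$generation), 300)
})

test_that("seeded runs are bit-reproducible", {
  r1 <- cma_es(sphere, rep(0.5, 6), -1, 1, sigma0 = 0.2, popsize = 8,
               max_gen = 40, seed = 9)
  r2 <- cma_es(sphere, rep(0.5, 6), -1, 1, sigma0 = 0.2, popsize = 8,
               max_gen = 40, seed = 9)
  expect_identical(r1$x_best, r2$x_best)
  expect_identical(r1$trace, r2$trace)
  r3 <- cma_es(sphere, rep(0.5, 6), -1, 1, sigma0 = 0.2, popsize = 8,
               max_gen = 40, seed = 10)
  expect_false(identical(r1$f_best, r3$f_best))
})

test_that("CMA-ES converges on a rotated convex quadratic", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  f <- function(x) as.numeric(t(x - 0.2) %*% A %*% (x - 0.2))
  res <- cma_es(f, rep(0, 5), -1, 1, sigma0 = 0.3, popsize = 10,
                max_gen = 250, seed = 2, stop_fitness = 1e-10)
  expect_lt(res$f_best, 1e-8)
  expect_equal(res$x_best, rep(0.2, 5), tolerance = 1e-3)
})

test_that("candidates are projected onto the box", {
  seen <- new.env(); seen$bad <- FALSE
  f <- function(x) { if (any(x < -1 - 1e-12 | x > 1 + 1e-12))
    seen$bad <- TRUE; sum(x^2) }
  cma_es(f, rep(0.9, 4), -1, 1, sigma0 = 0.5, popsize = 8, max_gen = 30,
         seed = 5)
  expect_false(seen$bad)
})

test_that("a zero-generation budget evaluates the start point", {
  layout <- controller_layout()
  x0 <- default_controller_params()
  cfg <- optimization_config(max_generations = 0)
  res <- optimize_controller(function(p) 42, x0, cfg)
  expect_equal(res$best_params, x0)
  expect_equal(res$best_cost, 42)
})

test_that("the reported best is the minimum across restarts", {
  layout <- controller_layout()
  x0 <- default_controller_params()
  f <- function(p) sum((p[1:5] - layout$lo[1:5])^2) + 1
  cfg <- optimization_config(population_size = 6, max_generations = 5,
                             n_parallel = 3, seed = 1)
  res <- optimize_controller(f, x0, cfg, free = layout$name[1:5])
  expect_equal(res$best_cost, min(res$restarts$best))
})

test_that("frozen parameters stay at their start values", {
  layout <- controller_layout()
  x0 <- default_controller_params()
  free <- layout$name[layout$block == "schedule"]
  cfg <- optimization_config(population_size = 6, max_generations = 5,
                             n_parallel = 1, seed = 3)
  res <- optimize_controller(function(p) sum(p[free]^2), x0, cfg,
                             free = free)
  frozen <- setdiff(layout$name, free)
  expect_equal(res$best_params[frozen], x0[frozen])
})

test_that("warm-start chains pass each solution to the next condition", {
  layout <- controller_layout()
  x0 <- default_controller_params()
  free <- layout$name[1:4]
  starts <- list()
  make_cost <- function(cond) {
    force(cond)
    function(p) sum((p[free] - cond$target)^2)
  }
  conds <- list(list(id = 1, target = 0.6), list(id = 2, target = 0.8))
  cfg <- optimization_config(population_size = 8, max_generations = 40,
                             n_parallel = 1, seed = 6)
  # restrict the chain to the same free subset via a wrapper
  out <- lapply(seq_along(conds), function(k) NULL)
  start <- x0
  for (k in seq_along(conds)) {
    res <- optimize_controller(make_cost(conds[[k]]), start, cfg,
                               free = free)
    out[[k]] <- res
    start <- res$best_params
  }
  expect_equal(unname(out[[1]]$best_params[free]), rep(0.6, 4),
               tolerance = 0.02)
  expect_equal(unname(out[[2]]$best_params[free]), rep(0.8, 4),
               tolerance = 0.02)

  # degenerate chain of length 1 behaves like a single optimization
  ch <- warm_start_chain(make_cost, conds[1], x0, cfg, layout = layout)
  expect_length(ch, 1)
  expect_false(ch[[1]]$no_solution)
})

test_that("warm_start_chain flags conditions stuck at the failure floor", {
  layout <- controller_layout()
  x0 <- default_controller_params()
  cfg <- optimization_config(population_size = 6, max_generations = 2,
                             n_parallel = 1, seed = 1)
  ch <- warm_start_chain(function(cond) function(p) 2e4,
                         list(list(id = "impossible")), x0, cfg,
                         layout = layout)
  expect_true(ch[[1]]$no_solution)
  expect_equal(unname(ch[[1]]$budget[["generations"]]), 2)
})
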