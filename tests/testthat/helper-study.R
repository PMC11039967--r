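# Desk-scale study shared by the directional acceptance checks: computed
# once per test run and cached. Budgets are the desk preset's: population
# 10, a few tens of generations per condition, warm-started chains from the
# shipped neutral controller.

.study_cache <- new.env(parent = emptyenv())

desk_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  grid <- c(list(condition_spec("neutral")),
            lapply(c(0.8, 0.7, 0.6, 0.5, 0.4),
                   function(s) condition_spec("weakness", vas_scale = s)),
            lapply(c(4, 3, 2),
                   function(p) condition_spec("pain", pain_threshold_bw = p)))
  cfg <- optimization_config(population_size = 10, max_generations = 25,
                             n_parallel = 1, seed = 101)
  .study_cache$study <- run_study(grid = grid, config = cfg,
                                  preset = desk_preset(),
                                  optimize_neutral = FALSE)
  .study_cache$study
}
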