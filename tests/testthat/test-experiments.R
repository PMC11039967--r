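test_that("condition specs enforce their kind's fields", {
  expect_error(condition_spec("weakness"), "vas_scale")
  expect_error(condition_spec("weakness", vas_scale = -1), "positive")
  expect_error(condition_spec("weakness", vas_scale = 0.8,
                              pain_threshold_bw = 2), "pain")
  expect_error(condition_spec("pain"), "pain_threshold_bw")
  expect_error(condition_spec("neutral", vas_scale = 0.5), "neutral")
  expect_identical(condition_spec("pain", pain_threshold_bw = 2)$pain_leg,
                   "l")
})

test_that("the default grid covers the weakness and pain sweeps", {
  g <- study_grid()
  kinds <- vapply(g, `[[`, "", "kind")
  expect_equal(sum(kinds == "neutral"), 1)
  expect_equal(vapply(g[kinds == "weakness"], `[[`, 0, "vas_scale"),
               c(0.8, 0.7, 0.6, 0.5, 0.4))
  expect_equal(vapply(g[kinds == "pain"], `[[`, 0, "pain_threshold_bw"),
               c(4, 3, 2))
})

test_that("weakness scales both vasti and their metabolic mass, nothing
           else", {
  m <- build_default_model()
  ap <- apply_condition(m, condition_spec("weakness", vas_scale = 0.5))
  i <- ap$model$muscles$group == "vas"
  expect_equal(ap$model$muscles$fmax[i], 0.5 * m$muscles$fmax[i])
  expect_equal(sum(i), 2)   # bilateral
  expect_equal(ap$model$muscles$fmax[!i], m$muscles$fmax[!i])
  mass0 <- muscle_mass(as.list(m$muscles[m$muscles$name == "vas_l", ]))
  mass1 <- muscle_mass(as.list(
    ap$model$muscles[ap$model$muscles$name == "vas_l", ]))
  expect_equal(mass1, 0.5 * mass0)
  # objective untouched
  expect_null(ap$objective$pain_threshold_bw)
})

test_that("pain conditions leave the model untouched and arm the cost", {
  m <- build_default_model()
  ap <- apply_condition(m, condition_spec("pain", pain_threshold_bw = 2))
  expect_identical(ap$model, m)
  expect_equal(ap$objective$pain_threshold_bw, 2)
  expect_identical(ap$objective$pain_leg, "l")
  # 2 BW on the default model is 1471.5 N
  expect_equal(ap$objective$pain_threshold_bw * body_weight(m), 1471.5)
})

test_that("the neutral condition is the identity", {
  m <- build_default_model()
  ap <- apply_condition(m, condition_spec("neutral"))
  expect_identical(ap$model, m)
  expect_identical(unclass(ap$objective),
                   unclass(objective_config()))
})

test_that("provenance hashes depend on parameter content only", {
  x <- default_controller_params()
  expect_identical(stwsim:::param_hash(x), stwsim:::param_hash(x))
  y <- x; y[5] <- y[5] + 1e-6
  expect_false(identical(stwsim:::param_hash(x), stwsim:::param_hash(y)))
})
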