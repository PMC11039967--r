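test_that("the generated model file rebuilds the default model", {
  f <- tempfile(fileext = ".yaml")
  default_model_file(f)
  cfg <- read_model_config(f)
  m <- build_default_model(cfg)
  expect_equal(m$total_mass, 75)
  expect_equal(nrow(m$dofs), 11)
  expect_equal(nrow(m$muscles), 20)
  m0 <- build_default_model()
  expect_equal(m$muscles$L0, m0$muscles$L0)
  unlink(f)
})

test_that("model file regeneration is byte-identical", {
  f1 <- tempfile(); f2 <- tempfile()
  default_model_file(f1)
  default_model_file(f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("every toy scene carries an executable oracle", {
  sc <- toy_scenes()
  expect_setequal(names(sc), c("pendulum", "double_pendulum",
                               "lever_muscle", "drop_test",
                               "seated_static"))
  for (s in sc) expect_false(is.null(s$oracle))
})

test_that("the lever-muscle isometric torque equals force times arm", {
  sc <- toy_scenes()$lever_muscle
  mus <- as.list(sc$model$muscles[1, ])
  mg <- muscle_geometry(sc$model, 0)
  F <- mtu_force(mus, mg$length[[1]], 0, a = 0.8)
  # generalized force the engine applies about the pin
  tau_engine <- unname(mg$arms[1, 1] * F)
  expect_equal(tau_engine, F * sc$oracle$arm, tolerance = 1e-12)
  expect_gt(F, 0)
})

test_that("the desk preset frees a strict subset of the parameters", {
  p <- desk_preset()
  layout <- controller_layout()
  expect_true(all(p$free %in% layout$name))
  expect_lt(length(p$free), nrow(layout))
  expect_false(any(grepl("^gait_", p$free)))
})

test_that("synthetic envelopes are bounded, seeded and degenerate cleanly", {
  e1 <- synthetic_envelopes(seed = 3)
  e2 <- synthetic_envelopes(seed = 3)
  expect_identical(e1, e2)
  expect_setequal(names(e1), MUSCLE_GROUPS)
  for (d in e1) {
    expect_true(all(d$lo <= d$hi))
    expect_true(all(d$mean >= 0 & d$mean <= 1))
    expect_true(all(d$lo >= 0 & d$hi <= 1))
  }
  e0 <- synthetic_envelopes(seed = 3, band = 0)
  expect_equal(e0$vas$lo, e0$vas$mean)
  expect_equal(e0$vas$hi, e0$vas$mean)
  e3 <- synthetic_envelopes(seed = 4)
  expect_false(identical(e1$vas$mean, e3$vas$mean))
})

test_that("the neutral warm start matches the controller layout", {
  x <- neutral_warm_start()
  layout <- controller_layout()
  expect_identical(names(x), layout$name)
  expect_true(all(x >= layout$lo - 1e-9 & x <= layout$hi + 1e-9))
})
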