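mdef <- list(fmax = 1000, lopt = 0.1, lslack = 0.2, vmax = 10)

test_that("curve anchors hold exactly", {
  expect_identical(force_length(1), 1)
  expect_identical(force_velocity(0), 1)
  expect_identical(force_passive(1), 0)
})

test_that("activation dynamics match the closed-form exponential", {
  tau <- muscle_constants()$tau_act
  a <- 0; dt <- 1e-3
  for (k in 1:200) a <- activation_step(1, a, dt)
  expect_equal(a, 1 - exp(-0.2 / tau), tolerance = 1e-6)
  # fixed point
  expect_equal(activation_step(0.5, 0.5, 0.01), 0.5)
  # monotone decay toward zero, never negative
  a <- 1
  prev <- a
  for (k in 1:100) {
    a <- activation_step(0, a, 5e-3)
    expect_lte(a, prev); expect_gte(a, 0)
    prev <- a
  }
})

test_that("mtu force reproduces hand-evaluated curve products", {
  # inactive at optimal length with no passive engagement
  expect_equal(mtu_force(mdef, L = 0.3, v = 0, a = 0), 0)
  # isometric at optimum gives fmax
  expect_equal(mtu_force(mdef, L = 0.3, v = 0, a = 1), 1000)
  # a = 0.5, ltilde = 0.9, vtilde = -0.2 (shortening)
  L <- 0.2 + 0.09
  v <- -0.2 * 0.1 * 10
  want <- 1000 * 0.5 * exp(-((0.9 - 1) / 0.45)^2) *
    (1 - 0.2) / (1 + 0.2 / 0.25)
  expect_equal(mtu_force(mdef, L, v, 0.5), want, tolerance = 1e-12)
  # slack muscle: fiber floored, passive zero, force ~ 0
  expect_lt(mtu_force(mdef, L = 0.19, v = 0, a = 1), 1000 * 0.01)
})

test_that("muscle mass follows the PCSA x density x fiber-length estimate", {
  expect_equal(muscle_mass(list(fmax = 2500, lopt = 0.10)), 1.0597,
               tolerance = 1e-12)
  m1 <- muscle_mass(list(fmax = 2500, lopt = 0.10))
  m2 <- muscle_mass(list(fmax = 1250, lopt = 0.10))
  expect_equal(m2, 0.5 * m1)
  expect_equal(muscle_mass(list(fmax = 0, lopt = 0.10)), 0)
})

test_that("metabolic rates are zero for a quiescent muscle and have no
           negative components", {
  r <- metabolic_rates(list(a = 0, F = 0, v = 0, lt = 1), mdef)
  expect_equal(unname(r), c(0, 0, 0, 0))
  set.seed(5)
  for (i in 1:50) {
    s <- list(a = runif(1), F = runif(1, 0, 2000), v = runif(1, -1, 1),
              lt = runif(1, 0.5, 1.5))
    expect_true(all(metabolic_rates(s, mdef) >= 0))
  }
})

test_that("positive work rate vanishes for a lengthening fiber", {
  r <- metabolic_rates(list(a = 0.5, F = 500, v = 0.2, lt = 1), mdef)
  expect_equal(unname(r[["Wdot"]]), 0)
  expect_equal(unname(r[["Sdot"]]), 0)
})

test_that("halving fmax halves mass-scaled heat rates and isometric force", {
  s <- list(a = 0.6, F = 300, v = -0.1, lt = 1.05)
  r1 <- metabolic_rates(s, mdef)
  r2 <- metabolic_rates(s, within(mdef, fmax <- fmax / 2))
  expect_equal(unname(r2[["Adot"]]), unname(r1[["Adot"]]) / 2)
  expect_equal(unname(r2[["Mdot"]]), unname(r1[["Mdot"]]) / 2)
  f1 <- mtu_force(mdef, 0.3, 0, 1)
  f2 <- mtu_force(within(mdef, fmax <- fmax / 2), 0.3, 0, 1)
  expect_equal(f2, f1 / 2)
})

test_that("force stays within physical bounds over random inputs", {
  set.seed(11)
  ceiling <- 1000 * (1.4 + 3)   # eccentric plateau + passive cap
  for (i in 1:200) {
    F <- mtu_force(mdef, L = runif(1, 0.15, 0.45), v = runif(1, -2, 2),
                   a = runif(1))
    expect_gte(F, 0)
    expect_lte(F, ceiling)
  }
})

test_that("force is continuous across zero velocity", {
  eps <- 1e-9
  f1 <- mtu_force(mdef, 0.3, -eps, 0.7)
  f2 <- mtu_force(mdef, 0.3, +eps, 0.7)
  expect_equal(f1, f2, tolerance = 1e-6)
})
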