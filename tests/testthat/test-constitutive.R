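test_that("force laws vanish at rest length and have the compression sign", {
  for (n in c(1, 3 / 2, 3)) {
    law <- force_law(k = 2.7, a = 1.3, n = n, eta = 0.8)
    expect_identical(spring_force(law, 1.3), 0)
    l <- c(0.2, 0.9, 1.2, 1.4, 2.5)
    expect_identical(sign(spring_force(law, l)), sign(law$a - l))
  }
})

test_that("force values match direct evaluation and the odd-symmetric extension", {
  expect_equal(spring_force(force_law(k = 1, a = 1, n = 1), 0.5), 0.5)
  # stretched cubic cell: sign(a - l) k |a - l|^n
  expect_equal(spring_force(force_law(k = 2, a = 1, n = 3), 1.5), -0.25)
  # Hertz law defined on both sides of the rest length
  lawh <- force_law(k = 2, a = 1, n = "hertz")
  expect_equal(spring_force(lawh, 0.75), 2 * 0.25^1.5)
  expect_equal(spring_force(lawh, 1.25), -2 * 0.25^1.5)
})

test_that("force derivative matches a symbolic/central-difference oracle", {
  expect_equal(spring_force_deriv(force_law(k = 3, a = 1, n = 1), c(0.3, 1, 2)),
               rep(-3, 3))
  expect_equal(spring_force_deriv(force_law(k = 1, a = 1, n = 3), 0.5), -0.75)
  expect_equal(spring_force_deriv(force_law(k = 1, a = 1, n = 3), 1), 0)
  set.seed(11)
  for (i in 1:20) {
    law <- force_law(k = runif(1, 0.5, 5), a = runif(1, 0.5, 3),
                     n = sample(c(1, 1.5, 2, 3), 1), eta = runif(1, 0.5, 2))
    l <- runif(1, 0.1, 2 * law$a)
    if (law$n < 1 && abs(l - law$a) < 1e-3) next
    h <- 1e-6 * law$a
    expect_equal(spring_force_deriv(law, l),
                 central_diff(function(x) spring_force(law, x), l, h),
                 tolerance = 1e-6)
  }
})

test_that("diffusivity reduces to alpha/q^2 for the linear law", {
  law <- force_law(k = 1, a = 1, n = 1, eta = 1)
  expect_equal(diffusivity(law, 2), 0.25)
  set.seed(3)
  q <- runif(100, 0.05, 10)
  law2 <- force_law(k = 4, a = 2, n = 1, eta = 1.6)
  expect_equal(diffusivity(law2, q) * q^2, rep(law2$alpha, 100))
})

test_that("diffusivity follows -F'(1/q)/(eta q^2) and degenerates for n > 1", {
  expect_equal(diffusivity(force_law(k = 1, a = 1, n = 3), 2), 0.1875)
  expect_equal(diffusivity(force_law(k = 7, a = 2, n = 3), 1 / 2), 0)
  law <- force_law(k = 2, a = 1.5, n = 3 / 2, eta = 2)
  q <- 0.9
  expect_equal(diffusivity(law, q),
               -spring_force_deriv(law, 1 / q) / (law$eta * q^2))
})

test_that("proliferation families follow their stated forms", {
  expect_identical(division_rate(proliferation_law("none"), c(0.5, 2)), c(0, 0))
  expect_identical(division_rate(NULL, 1.5), 0)
  expect_equal(division_rate(proliferation_law("constant", beta = 0.001), 7), 0.001)
  expect_equal(division_rate(proliferation_law("length_proportional", beta = 0.002,
                                               a_ref = 1), 1), 0.002)
  expect_equal(division_rate(proliferation_law("length_proportional", beta = 0.002,
                                               a_ref = 2), 3), 0.003)
  # target-length family: monotone increasing, saturating at beta
  plaw <- proliferation_law("target_length", beta = 0.01, a_ref = 1)
  l <- seq(0.1, 5, by = 0.1)
  g <- division_rate(plaw, l)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 0.01))
  expect_equal(division_rate(plaw, 1), 0.005) # half-saturation at the target
  # every family returns 0 when beta = 0
  for (fam in c("constant", "length_proportional", "target_length"))
    expect_identical(division_rate(proliferation_law(fam, beta = 0), l), rep(0, length(l)))
})

test_that("custom proliferation hook is applied and validated", {
  plaw <- proliferation_law("custom", beta = 1, rate_fn = function(l) 0.1 * l^2)
  expect_equal(division_rate(plaw, c(1, 2)), c(0.1, 0.4))
  bad <- proliferation_law("custom", beta = 1, rate_fn = function(l) -l)
  expect_error(division_rate(bad, 1), "non-negative")
  expect_error(proliferation_law("custom"), "rate_fn")
})

test_that("invalid arguments are rejected", {
  expect_error(force_law(k = -1), "positive")
  expect_error(force_law(n = 0), "positive")
  expect_error(spring_force(force_law(), -0.5), "positive")
  expect_error(spring_force_deriv(force_law(), 0), "positive")
  expect_error(diffusivity(force_law(), -2), "positive")
  expect_error(division_rate(proliferation_law("constant", beta = 1), 0), "positive")
  expect_error(proliferation_law("constant", beta = -1), "non-negative")
  # derivative undefined at the rest length for sub-linear exponents
  expect_error(spring_force_deriv(force_law(n = 0.5), 1), "not defined")
})
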