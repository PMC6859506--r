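test_that("net velocities follow the overdamped force balance", {
  law <- force_law(k = 1, a = 2, n = 1, eta = 1)
  # uniform spacing at the rest length: equilibrium
  eq <- cell_chain(c(0, 2, 4, 6))
  expect_equal(net_velocity(eq, law), rep(0, 4))
  # worked example: alpha = 1, a = 2, nodes (0, 1, 3)
  ch <- cell_chain(c(0, 1, 3))
  expect_equal(net_velocity(ch, law), c(0, 1, 0))
  expect_equal(net_velocity(ch, law, path = "linear"), c(0, 1, 0))
  # single cell: dx/dt = -alpha * (x - a)
  law2 <- force_law(k = 3, a = 1, n = 1, eta = 2)
  single <- cell_chain(c(0, 1.25))
  expect_equal(net_velocity(single, law2), c(0, -law2$alpha * 0.25))
  expect_error(net_velocity(ch, force_law(n = 3), path = "linear"), "n = 1")
})

test_that("euler_step advances positions and guards the ordering", {
  law <- force_law(k = 1, a = 2, n = 1)
  eq <- cell_chain(c(0, 2, 4))
  stepped <- euler_step(eq, law, 0.5)
  expect_equal(stepped$x, eq$x)
  expect_equal(stepped$t, 0.5)
  ch <- cell_chain(c(0, 1, 3))
  expect_equal(euler_step(ch, law, 0.001)$x, c(0, 1.001, 3))
  stiff <- force_law(k = 1e4, a = 2, n = 1)
  expect_error(euler_step(cell_chain(c(0, 1, 1.01, 3)), stiff, 0.1), "ordering")
})

test_that("a single cell relaxes with the exact scalar decay rate", {
  law <- force_law(k = 1.7, a = 1, n = 1)
  dt <- 0.01
  ch <- cell_chain(c(0, 1.5))
  for (i in 1:100) ch <- euler_step(ch, law, dt)
  expect_equal(ch$x[2] - 1, 0.5 * (1 - law$alpha * dt)^100, tolerance = 1e-12)
})

test_that("forward-Euler trajectories converge to the exact linear ODE solution at first order", {
  law <- force_law(k = 1, a = 2, n = 1)
  x0 <- seq(0, 8, by = 1)  # 8 compressed cells
  exact <- linear_chain_exact(x0, law, 1)
  err <- sapply(c(0.01, 0.005), function(dt) {
    traj <- simulate_chain(cell_chain(x0), law, NULL, dt, 1, 1000L)
    max(abs(traj$final_chain$x - exact))
  })
  expect_lt(err[1], 0.05 * law$alpha)      # small error at dt = 0.01
  expect_equal(err[1] / err[2], 2, tolerance = 0.25)  # halves with dt
})

test_that("general and linear code paths agree to rounding for n = 1", {
  law <- force_law(k = 15 * (15 / 45)^2, a = 3, n = 1)
  ch <- compressed_chain(15, 30)
  tg <- simulate_chain(ch, law, NULL, 1e-3, 50, 5000L)
  tl <- simulate_chain(ch, law, NULL, 1e-3, 50, 5000L, path = "linear")
  expect_equal(tg$final_chain$x[-1] / tl$final_chain$x[-1], rep(1, 15),
               tolerance = 1e-12)
})

test_that("single-step R operations replay the compiled simulation exactly", {
  law <- force_law(k = 2, a = 1.2, n = 3, eta = 1.5)
  plaw <- proliferation_law("length_proportional", beta = 0.5, a_ref = 1.2)
  set.seed(42)
  ch0 <- cell_chain(c(0, cumsum(runif(10, 0.5, 1.5))))
  set.seed(7)
  chR <- ch0
  for (s in 1:300) {
    chR <- euler_step(chR, law, 0.01)
    i <- sample_division(chR, plaw, 0.01)
    if (!is.null(i)) chR <- divide_cell(chR, i)
  }
  trC <- simulate_chain(ch0, law, plaw, 0.01, 3, 300L, seed = 7)
  expect_gt(chR$N, ch0$N)  # divisions actually occurred
  expect_identical(chR$x, trC$final_chain$x)
})

test_that("division sampling has the prescribed event and selection probabilities", {
  dt <- 0.01
  ch <- compressed_chain(5, 5)
  expect_null(sample_division(ch, proliferation_law("constant", beta = 0), dt))
  plaw <- proliferation_law("constant", beta = 0.8)
  p <- 5 * 0.8 * dt
  set.seed(123)
  n_draws <- 4e4
  events <- sum(replicate(n_draws, !is.null(sample_division(ch, plaw, dt))))
  se <- sqrt(n_draws * p * (1 - p))
  expect_lt(abs(events - n_draws * p), 3 * se)

  # conditional selection proportional to G_i: cell 1 twice the length of cell 2
  chain2 <- cell_chain(c(0, 2, 3))
  plaw2 <- proliferation_law("length_proportional", beta = 3, a_ref = 1)
  set.seed(99)
  picks <- replicate(2e4, sample_division(chain2, plaw2, 0.015))
  picks <- unlist(picks[!vapply(picks, is.null, logical(1))])
  p1 <- 2 / 3
  se1 <- sqrt(p1 * (1 - p1) / length(picks))
  expect_lt(abs(mean(picks == 1L) - p1), 3 * se1)

  expect_error(sample_division(ch, proliferation_law("constant", beta = 30), dt),
               "time step too large")
})

test_that("simulation honours the mechanics-then-division contract and determinism", {
  law <- force_law(k = 15, a = 1, n = 1)
  plaw <- proliferation_law("constant", beta = 0.02)
  ch <- compressed_chain(20, 20)  # at rest length: only divisions move things
  t1 <- simulate_chain(ch, law, plaw, 1e-3, 10, 1L, seed = 5)
  t2 <- simulate_chain(ch, law, plaw, 1e-3, 10, 1L, seed = 5)
  expect_identical(t1$L, t2$L)
  expect_identical(t1$N, t2$N)
  # N is non-decreasing and moves by single divisions
  expect_true(all(diff(t1$N) %in% c(0L, 1L)))
  # without proliferation N is constant and an equilibrium chain is static
  t0 <- simulate_chain(ch, law, NULL, 1e-3, 5, 500L)
  expect_true(all(t0$N == 20L))
  expect_true(all(t0$L == 20))
})

test_that("a compressed chain expands monotonically to the rest configuration", {
  law <- force_law(k = 15 * (15 / 45)^2, a = 3, n = 1)
  traj <- simulate_chain(compressed_chain(15, 30), law, NULL, 1e-3, 200, 2000L)
  expect_true(all(diff(traj$L) > 0))
  relax <- simulate_to_relaxation(compressed_chain(15, 30), law, dt = 1e-3)
  expect_true(relax$relaxed)
  expect_equal(tail(relax$L, 1), 45, tolerance = 5e-3)
  # an equilibrium chain is immediately flagged as relaxed
  eq <- simulate_to_relaxation(compressed_chain(15, 45), law, dt = 1e-3)
  expect_true(eq$relaxed)
  expect_equal(eq$t_end, 25)
})

test_that("ensembles summarise realisations with reproducible seeds", {
  law <- force_law(k = 15, a = 1, n = 1)
  ch <- compressed_chain(10, 8)
  ens0 <- run_ensemble(ch, law, NULL, 1e-3, 1, 100L, seed = 2, n_realisations = 3)
  expect_true(all(ens0$std_L == 0))  # deterministic dynamics
  plaw <- proliferation_law("constant", beta = 0.05)
  one <- run_ensemble(ch, law, plaw, 1e-3, 2, 200L, seed = 3, n_realisations = 1)
  traj <- simulate_chain(ch, law, plaw, 1e-3, 2, 200L, seed = 3 + 1)
  expect_identical(one$mean_N, as.numeric(traj$N))
  expect_true(all(one$std_N == 0))
  ens <- run_ensemble(ch, law, plaw, 1e-3, 2, 200L, seed = 3, n_realisations = 5)
  expect_identical(ens$mean_N[1], 10)
  expect_true(all(ens$std_N >= 0))
})
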