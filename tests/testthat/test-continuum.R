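test_that("initial density projection is piecewise linear with the right mass", {
  ch <- compressed_chain(15, 30)  # uniform spacing 2
  d <- initial_density_from_chain(ch, 101)
  expect_equal(d$L0, 30)
  expect_equal(d$q0, rep(0.5, 101))
  expect_equal(trapz_oracle(d$X, d$q0), 15, tolerance = 1e-12)
  set.seed(8)
  ch2 <- cell_chain(c(0, cumsum(runif(40, 0.8, 1.2))))
  d2 <- initial_density_from_chain(ch2, 401)
  expect_equal(trapz_oracle(d2$X, d2$q0), 40, tolerance = 2 / 40)
})

test_that("growth fields vanish without proliferation and match the uniform closed form", {
  st <- state_from_chain(compressed_chain(15, 30), 101)
  gf0 <- growth_fields(st, NULL)
  expect_identical(gf0$source, rep(0, 101))
  expect_identical(gf0$E, rep(0, 101))
  # constant G = beta on uniform q over [0, L]: I(x) = beta q x, E = beta x / (2 q)
  beta <- 0.002
  gf <- growth_fields(st, proliferation_law("constant", beta = beta))
  expect_equal(gf$integral, beta * 0.5 * st$X, tolerance = 1e-12)
  expect_equal(gf$E, beta * st$X / (2 * 0.5), tolerance = 1e-12)
  expect_identical(gf$E[1], 0)
})

test_that("uniform rest-density states are fixed points of the implicit step", {
  for (n in c(1, 3)) {
    a <- 1
    law <- force_law(k = 15, a = a, n = n)
    st <- state_from_chain(compressed_chain(30, 30), 101)  # q = 1/a exactly
    out <- advance_state(st, law, cfg = pde_config(M = 101L))
    expect_equal(out$q, st$q, tolerance = 1e-12)
    expect_equal(free_boundary(out), 30, tolerance = 1e-10)
  }
})

test_that("the continuum solve conserves total cell number without proliferation", {
  law <- force_law(k = 15 * (15 / 45)^2, a = 3, n = 1)
  ch <- compressed_chain(15, 30)
  cfg <- pde_config()
  sol <- solve_pde(ch, law = law, cfg = cfg, t_end = 100)
  drift <- abs(sol$N - sol$N[1]) / sol$N[1]
  expect_lt(max(drift), 1e-6)
  # per-step drift of the advanced state stays at solver tolerance
  st <- state_from_chain(ch, cfg$M)
  N0 <- total_cells(st)
  st1 <- advance_state(st, law, cfg = cfg)
  expect_lt(abs(total_cells(st1) - N0), 10 * cfg$picard_tol)
})

test_that("the solver is deterministic", {
  law <- force_law(k = 5 / 3, a = 3, n = 1)
  ch <- compressed_chain(15, 30)
  s1 <- solve_pde(ch, law = law, cfg = pde_config(M = 101L), t_end = 20)
  s2 <- solve_pde(ch, law = law, cfg = pde_config(M = 101L), t_end = 20)
  expect_identical(s1$L, s2$L)
  expect_identical(s1$final_state$q, s2$final_state$q)
})

test_that("the free-boundary condition residual vanishes where it should", {
  law <- force_law(k = 15, a = 2, n = 1)
  X <- seq(0, 30, length.out = 101)
  uniform <- lagrangian_state(X, X, rep(1 / 2, 101))
  expect_equal(boundary_residual(uniform, law), 0)
  # after a converged solve the discrete condition holds to solver accuracy
  lawc <- force_law(k = 5 / 3, a = 3, n = 1)
  sol <- solve_pde(compressed_chain(15, 30), law = lawc, cfg = pde_config(),
                   t_end = 50)
  expect_lt(max(abs(sol$boundary_residual[-1])), 1e-6)
  expect_lt(abs(boundary_residual(sol$final_state, lawc)), 1e-6)
  # legacy mode pins the boundary density at 1/a
  leg <- solve_pde(compressed_chain(15, 30), law = lawc, cfg = pde_config(),
                   t_end = 50, legacy_boundary = TRUE)
  expect_equal(leg$final_state$q[201], 1 / 3, tolerance = 1e-12)
})

test_that("free boundary and total cells read off the state", {
  X <- seq(0, 30, length.out = 101)
  st <- lagrangian_state(X, X, rep(1, 101))
  expect_equal(free_boundary(st), 30)
  expect_equal(total_cells(st), 30)
})

test_that("a compressed population expands to the rest configuration", {
  law <- force_law(k = 5 / 3, a = 3, n = 1)
  sol <- solve_pde(compressed_chain(15, 30), law = law, cfg = pde_config(),
                   t_end = 400)
  expect_true(all(diff(sol$L) > 0))
  expect_equal(tail(sol$L, 1), 45, tolerance = 5e-3)          # L -> N(0) a
  expect_equal(sol$final_state$q, rep(1 / 3, 201), tolerance = 5e-3)  # q -> 1/a
})

test_that("the boundary motion integrates the characteristic speed", {
  law <- force_law(k = 5 / 3, a = 3, n = 1)
  sol <- solve_pde(compressed_chain(15, 30), law = law,
                   cfg = pde_config(M = 401L, dt = 5e-3), t_end = 60,
                   snapshots = TRUE)
  # dL/dT from records vs -D(q)/q dq/dx evaluated at the front
  ts <- sol$times
  mid <- seq(2, length(ts) - 1)
  dLdT <- (sol$L[mid + 1] - sol$L[mid - 1]) / (ts[mid + 1] - ts[mid - 1])
  speed <- sapply(mid, function(i) {
    st <- sol$states[[i]]
    M <- length(st$q)
    h <- st$X[2] - st$X[1]
    gx <- (3 * st$Gamma[M] - 4 * st$Gamma[M - 1] + st$Gamma[M - 2]) / (2 * h)
    qx <- (3 * st$q[M] - 4 * st$q[M - 1] + st$q[M - 2]) / (2 * h) / gx
    -diffusivity(law, st$q[M]) / st$q[M] * qx
  })
  expect_equal(dLdT, speed, tolerance = 0.05)
})

test_that("with constant division rate the cell number grows exponentially", {
  law <- force_law(k = 15, a = 1, n = 1)
  plaw <- proliferation_law("constant", beta = 1e-3)
  cfg <- pde_config()
  sol <- solve_pde(compressed_chain(30, 30), law = law, plaw = plaw, cfg = cfg,
                   t_end = 200)
  expect_equal(sol$N, 30 * exp(1e-3 * sol$times), tolerance = 10 * cfg$dt)
  # discrete-in-time growth identity: dN/dT equals the growth integral
  gf <- growth_fields(sol$final_state, plaw)
  gx <- sol$final_state$mass / sol$final_state$q
  rate <- trapz_oracle(sol$final_state$X, gf$source * gx)
  dN <- (sol$N[length(sol$N)] - sol$N[length(sol$N) - 1]) /
    (sol$times[length(sol$N)] - sol$times[length(sol$N) - 1])
  expect_equal(dN, rate, tolerance = 0.02)
})

test_that("refining the grid and the time step converges at the expected orders", {
  law <- force_law(k = 5 / 3, a = 3, n = 1)
  ch <- compressed_chain(15, 30)
  # spatial self-convergence at fixed small dt: O(1/M^2)
  Ls <- sapply(c(51L, 101L, 201L), function(M)
    tail(solve_pde(ch, law = law, cfg = pde_config(M = M, dt = 2e-3), t_end = 20)$L, 1))
  r_space <- abs(Ls[1] - Ls[2]) / abs(Ls[2] - Ls[3])
  expect_gt(r_space, 2.5)
  # temporal self-convergence at fixed grid: first order
  Lt <- sapply(c(0.04, 0.02, 0.01), function(dt)
    tail(solve_pde(ch, law = law, cfg = pde_config(M = 101L, dt = dt), t_end = 20)$L, 1))
  r_time <- abs(Lt[1] - Lt[2]) / abs(Lt[2] - Lt[3])
  expect_gt(r_time, 1.4)
  expect_lt(r_time, 3)
})

test_that("solver errors are informative", {
  law <- force_law(k = 5 / 3, a = 3, n = 1)
  ch <- compressed_chain(15, 30)
  expect_error(solve_pde(ch, law = law, cfg = pde_config(picard_max = 1L), t_end = 1),
               "Picard")
  expect_error(solve_pde(rep(0.5, 100), L0 = 30, law = law,
                         cfg = pde_config(M = 201L), t_end = 1), "cfg\\$M")
  expect_error(lagrangian_state(seq(0, 1, length.out = 11),
                                seq(0, 1, length.out = 11), rep(-1, 11)),
               "positive")
  expect_error(lagrangian_state(seq(0, 1, length.out = 11),
                                rev(seq(0, 1, length.out = 11)), rep(1, 11)),
               "increasing|pinned")
  plaw <- proliferation_law("constant", beta = 200)
  expect_error(solve_pde(ch, law = law, plaw = plaw,
                         cfg = pde_config(), t_end = 1), "time step too large")
})
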