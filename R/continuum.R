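#' Numerical configuration for the continuum solver
#'
#' @param M Number of grid points on the fixed Lagrangian interval
#'   `[0, L(0)]` (at least 5).
#' @param dt Time step of the implicit stepper.
#' @param picard_tol Convergence tolerance (max-norm change in the density
#'   iterate) of the Picard iteration.
#' @param picard_max Maximum Picard sweeps per step.
#' @return A `pde_config` list.
#' @export
pde_config <- function(M = 201L, dt = 0.01, picard_tol = 1e-10, picard_max = 600L) {
  if (!is.numeric(M) || M < 5) stop("`M` must be at least 5", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (picard_tol <= 0) stop("`picard_tol` must be positive", call. = FALSE)
  if (picard_max < 1) stop("`picard_max` must be at least 1", call. = FALSE)
  structure(list(M = as.integer(M), dt = dt, picard_tol = picard_tol,
                 picard_max = as.integer(picard_max)),
            class = "pde_config")
}

# d/dX on a uniform grid: central interior, second-order one-sided ends
# (mirrors the compiled solver's stencils)
grid_deriv_r <- function(f, h) {
  M <- length(f)
  d <- numeric(M)
  d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  d[2:(M - 1)] <- (f[3:M] - f[1:(M - 2)]) / (2 * h)
  d[M] <- (3 * f[M] - 4 * f[M - 1] + f[M - 2]) / (2 * h)
  d
}

#' Continuum state in Lagrangian coordinates
#'
#' The free-boundary problem is solved on the fixed reference interval
#' `X` in `[0, L(0)]` through the map `x = Gamma(X, T)`, which carries the
#' reference interval onto the physical domain `[0, L(T)]`. The state holds
#' the map values `Gamma`, the density `q` at the grid points, and the time
#' `T`. At `T = 0` the map is the identity.
#'
#' @param X Uniform grid on `[0, L(0)]`.
#' @param Gamma Map values at the grid points; `Gamma[1]` must be 0 and the
#'   map strictly increasing.
#' @param q Density values, positive.
#' @param T Time.
#' @param mass Optional per-node mass densities `q * Gamma_X` carried by the
#'   solver; recomputed from the fields when absent.
#' @export
lagrangian_state <- function(X, Gamma, q, T = 0, mass = NULL) {
  M <- length(X)
  if (M < 5) stop("the grid needs at least 5 points", call. = FALSE)
  if (length(Gamma) != M || length(q) != M)
    stop("`X`, `Gamma` and `q` must have the same length", call. = FALSE)
  if (X[1] != 0 || any(diff(X) <= 0))
    stop("`X` must be an increasing grid starting at 0", call. = FALSE)
  if (Gamma[1] != 0) stop("the map must be pinned: Gamma[1] == 0", call. = FALSE)
  if (any(diff(Gamma) <= 0))
    stop("the map must be strictly increasing in X", call. = FALSE)
  if (any(q <= 0)) stop("density must be positive everywhere", call. = FALSE)
  if (T == 0 && max(abs(Gamma - X)) > 1e-12 * max(X))
    stop("at T = 0 the map must be the identity (Gamma == X)", call. = FALSE)
  h <- X[2] - X[1]
  if (max(abs(diff(X) - h)) > 1e-9 * h)
    stop("`X` must be uniformly spaced", call. = FALSE)
  if (is.null(mass)) mass <- q * grid_deriv_r(Gamma, h)
  structure(list(X = X, Gamma = Gamma, q = q, T = T, h = h, mass = mass),
            class = "lagrangian_state")
}

#' @export
print.lagrangian_state <- function(x, ...) {
  cat(sprintf("<lagrangian_state> M = %d, T = %g, L = %g, N = %g\n",
              length(x$X), x$T, free_boundary(x), total_cells(x)))
  invisible(x)
}

#' Initial continuum density from a cell chain
#'
#' Projects the node-based density samples of a chain onto a uniform grid of
#' `M` points spanning `[0, x_N]` by piecewise-linear interpolation.
#'
#' @param chain A [cell_chain()].
#' @param M Number of grid points.
#' @return A list with the grid `X`, interpolated densities `q0`, and the
#'   initial domain length `L0 = x_N`.
#' @export
initial_density_from_chain <- function(chain, M = 201L) {
  nd <- node_density(chain)
  L0 <- chain$x[chain$N + 1]
  X <- seq(0, L0, length.out = M)
  q0 <- approx(nd$positions, nd$q, xout = X)$y
  list(X = X, q0 = q0, L0 = L0)
}

#' Initial Lagrangian state from a cell chain
#'
#' @inheritParams initial_density_from_chain
#' @export
state_from_chain <- function(chain, M = 201L) {
  d <- initial_density_from_chain(chain, M)
  lagrangian_state(d$X, d$X, d$q0, T = chain$t)
}

#' Proliferation source, growth integral and transport coefficient E
#'
#' For a proliferative population the continuum model gains a source
#' `q G(1/q)` and an extra transport coefficient
#' `E(q) = I / (2 q^2)`, where `I(x)` is the cumulative proliferation
#' integral of `q G(1/q)` from the origin, evaluated here in Lagrangian
#' coordinates as the cumulative trapezoidal integral of
#' `q G(1/q) Gamma_X` along the grid.
#'
#' @param state A [lagrangian_state()].
#' @param plaw A [proliferation_law()] or `NULL`.
#' @return A list with `source` (`q G(1/q)` at the grid points), `integral`
#'   (`I`, zero at the origin) and `E`.
#' @export
growth_fields <- function(state, plaw = NULL) {
  if (any(state$q <= 0)) stop("invalid state: density must be positive", call. = FALSE)
  g <- division_rate(plaw, 1 / state$q)
  src <- state$q * g
  gx <- grid_deriv_r(state$Gamma, state$h)
  I <- pracma::cumtrapz(state$X, src * gx)[, 1]
  list(source = src, integral = I, E = I / (2 * state$q^2))
}

#' Free-boundary position of a continuum state
#'
#' @param state A [lagrangian_state()].
#' @return `L(T) = Gamma(L(0), T)`, the physical position of the moving
#'   front.
#' @export
free_boundary <- function(state) state$Gamma[length(state$Gamma)]

#' Total cell number of a continuum state
#'
#' @param state A [lagrangian_state()].
#' @return The trapezoidal integral of `q Gamma_X` over the reference grid,
#'   i.e. `N(T) = int_0^L(T) q dx`.
#' @export
total_cells <- function(state) {
  gx <- grid_deriv_r(state$Gamma, state$h)
  pracma::trapz(state$X, state$q * gx)
}

#' Residual of the free-boundary condition
#'
#' Evaluates, with the solver's one-sided differences, the mass-conserving
#' boundary condition
#' \deqn{\frac{1}{\eta}F(1/q) + \frac{1}{q \Gamma_X}\left(\frac{D(q)}{2} + E(q)\right)\frac{\partial q}{\partial X} = 0}
#' at `X = L(0)`. In legacy mode the residual is `q(L(0)) - 1/a` (the
#' prior-work Dirichlet condition).
#'
#' @param state A [lagrangian_state()].
#' @param law A [force_law()].
#' @param plaw A [proliferation_law()] or `NULL`.
#' @param legacy_boundary Use the prior-work condition `q = 1/a`.
#' @export
boundary_residual <- function(state, law, plaw = NULL, legacy_boundary = FALSE) {
  M <- length(state$X)
  if (legacy_boundary) return(state$q[M] - 1 / law$a)
  h <- state$h
  G <- state$Gamma
  m <- state$mass
  # expressed through the mass identity q = m / Gamma_X, with the same
  # one-sided stencils used by the solver's boundary closure
  gx_end <- (3 * G[M] - 4 * G[M - 1] + G[M - 2]) / (2 * h)
  gxx_end <- (2 * G[M] - 5 * G[M - 1] + 4 * G[M - 2] - G[M - 3]) / h^2
  mx_end <- (3 * m[M] - 4 * m[M - 1] + m[M - 2]) / (2 * h)
  E_end <- growth_fields(state, plaw)$E[M]
  qM <- state$q[M]
  spring_force(law, gx_end / m[M]) / law$eta +
    (diffusivity(law, qM) / 2 + E_end) *
      (mx_end / (m[M] * gx_end) - gxx_end / gx_end^2)
}

run_pde_cpp <- function(state, law, plaw, cfg, n_steps, record_every,
                        legacy_boundary, snapshots) {
  pde_run_cpp(state$q, state$Gamma, state$mass, state$T, state$h,
              law$k, law$a, law$n, law$eta,
              plaw_family_code(plaw),
              if (is.null(plaw)) 0 else plaw$beta,
              if (is.null(plaw)) 1 else plaw$a_ref,
              if (is.null(plaw)) 4 else plaw$shape,
              if (!is.null(plaw) && plaw$family == "custom") plaw$rate_fn else NULL,
              cfg$dt, as.integer(n_steps), as.integer(record_every),
              cfg$picard_tol, cfg$picard_max, legacy_boundary, snapshots)
}

#' One implicit time step of the continuum model
#'
#' Advances the coupled map/density system by one backward-Euler step,
#' iterating the lagged nonlinear coefficients (Picard) to `picard_tol`.
#'
#' @param state A [lagrangian_state()].
#' @param law A [force_law()].
#' @param plaw A [proliferation_law()] or `NULL`.
#' @param cfg A [pde_config()].
#' @param legacy_boundary Use the prior-work `q = 1/a` boundary condition.
#' @return The updated [lagrangian_state()] with `T` advanced by `cfg$dt`.
#' @export
advance_state <- function(state, law, plaw = NULL, cfg = pde_config(),
                          legacy_boundary = FALSE) {
  raw <- run_pde_cpp(state, law, plaw, cfg, 1L, 1L, legacy_boundary, FALSE)
  lagrangian_state(state$X, raw$Gamma_final, raw$q_final, T = state$T + cfg$dt,
                   mass = raw$mass_final)
}

#' Solve the free-boundary continuum model
#'
#' Solves the coarse-grained density equation with its mass-conserving
#' free-boundary condition (or, in legacy mode, the prior-work `q = 1/a`
#' condition) from a given initial density, recording the free-boundary
#' position, total cell number, boundary-condition residual and Picard sweep
#' counts along the way.
#'
#' @param q0 Initial density on a uniform grid over `[0, L0]` (length
#'   `cfg$M`), or a [cell_chain()] from which the initial density is
#'   projected.
#' @param L0 Initial domain length (ignored when `q0` is a chain).
#' @param law A [force_law()].
#' @param plaw A [proliferation_law()] or `NULL`.
#' @param cfg A [pde_config()].
#' @param t_end Final time.
#' @param record_every Recording stride in steps; default gives about 100
#'   records.
#' @param legacy_boundary Use the prior-work boundary condition.
#' @param snapshots Keep `(Gamma, q)` snapshots at recorded times.
#' @return A `pde_solution`: `times`, `L`, `N`, `boundary_residual`,
#'   `picard_iters`, the `final_state`, and optional `states`.
#' @export
solve_pde <- function(q0, L0 = NULL, law, plaw = NULL, cfg = pde_config(),
                      t_end, record_every = NULL, legacy_boundary = FALSE,
                      snapshots = FALSE) {
  if (inherits(q0, "cell_chain")) {
    state <- state_from_chain(q0, cfg$M)
  } else {
    if (is.null(L0)) stop("`L0` is required when `q0` is a density vector", call. = FALSE)
    if (length(q0) != cfg$M)
      stop("`q0` must have `cfg$M` entries on the uniform grid over [0, L0]", call. = FALSE)
    X <- seq(0, L0, length.out = cfg$M)
    state <- lagrangian_state(X, X, q0)
  }
  n_steps <- as.integer(round(t_end / cfg$dt))
  if (n_steps < 1) stop("`t_end` must cover at least one time step", call. = FALSE)
  if (is.null(record_every)) record_every <- max(1L, n_steps %/% 100L)
  raw <- run_pde_cpp(state, law, plaw, cfg, n_steps, record_every,
                     legacy_boundary, snapshots)
  states <- NULL
  if (snapshots)
    states <- lapply(seq_along(raw$times), function(i)
      lagrangian_state(state$X, raw$snapshots[[i]]$Gamma, raw$snapshots[[i]]$q,
                       T = raw$times[i]))
  structure(list(times = raw$times, L = raw$L, N = raw$N,
                 boundary_residual = raw$boundary_residual,
                 picard_iters = raw$picard_iters,
                 final_state = lagrangian_state(state$X, raw$Gamma_final,
                                                raw$q_final,
                                                T = raw$times[length(raw$times)],
                                                mass = raw$mass_final),
                 states = states, cfg = cfg, legacy_boundary = legacy_boundary),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<pde_solution> %d records over T in [%g, %g]; L: %g -> %g; N: %g -> %g\n",
              n, x$times[1], x$times[n], x$L[1], x$L[n], x$N[1], x$N[n]))
  invisible(x)
}
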