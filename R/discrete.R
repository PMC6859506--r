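#' Overdamped node velocities
#'
#' Net velocity of each node under the force law: the pinned node is static,
#' an interior node moves with `[F(l_i) - F(l_{i+1})] / eta` where `l_i` is
#' the length of the cell to its left, and the free-boundary node feels only
#' its left neighbour, `F(l_N) / eta`. With `path = "linear"` the specialised
#' linear-law stencil `alpha * (x_{i-1} - 2 x_i + x_{i+1})` is used instead
#' (only valid for `n = 1`).
#'
#' @param chain A [cell_chain()].
#' @param law A [force_law()].
#' @param path `"general"` (force differences) or `"linear"` (linear-law
#'   stencil).
#' @return Velocities for nodes `0..N`.
#' @export
net_velocity <- function(chain, law, path = c("general", "linear")) {
  path <- match.arg(path)
  x <- chain$x
  N <- chain$N
  v <- numeric(N + 1)
  if (path == "linear") {
    if (law$n != 1)
      stop("the linear path is only valid for force-law exponent n = 1", call. = FALSE)
    if (N > 1) {
      i <- 2:N
      v[i] <- law$alpha * (x[i - 1] - 2 * x[i] + x[i + 1])
    }
    v[N + 1] <- law$alpha * (x[N] - x[N + 1] + law$a)
  } else {
    f <- spring_force(law, diff(x))
    if (N > 1) v[2:N] <- (f[1:(N - 1)] - f[2:N]) / law$eta
    v[N + 1] <- f[N] / law$eta
  }
  v
}

#' One forward-Euler step of the chain mechanics
#'
#' @inheritParams net_velocity
#' @param dt Time step, positive.
#' @return The updated [cell_chain()] with `t` advanced by `dt`.
#' @export
euler_step <- function(chain, law, dt, path = c("general", "linear")) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  x <- chain$x + dt * net_velocity(chain, law, path)
  bad <- which(diff(x) <= 0)
  if (length(bad))
    stop(sprintf("node ordering violated at index %d: time step too large for this stiffness",
                 bad[1]), call. = FALSE)
  chain$x <- x
  chain$t <- chain$t + dt
  chain
}

#' Sample a division event for one time step
#'
#' Implements the constant-time-step division check: an event occurs with
#' probability `sum(G_i) * dt`, and conditional on an event cell `i` is
#' selected with probability `G_i / sum(G_j)`, where `G_i = G(x_i - x_{i-1})`.
#' At most one cell divides per step. Uses the current R random number
#' stream; no draws are consumed when the total rate is zero.
#'
#' @param chain A [cell_chain()].
#' @param plaw A [proliferation_law()].
#' @param dt Time step; `sum(G) * dt` must be below 1.
#' @return The dividing cell index, or `NULL` if no division occurs.
#' @export
sample_division <- function(chain, plaw, dt) {
  g <- division_rate(plaw, cell_lengths(chain))
  total <- sum(g)
  if (total * dt >= 1)
    stop("sum of division rates times dt is >= 1: time step too large", call. = FALSE)
  if (total <= 0) return(NULL)
  if (runif(1) >= total * dt) return(NULL)
  u <- runif(1) * total
  i <- match(TRUE, u < cumsum(g))
  if (is.na(i)) i <- length(g)
  i
}

as_trajectory <- function(raw, dt, snapshots) {
  chains <- NULL
  if (snapshots)
    chains <- lapply(seq_along(raw$times), function(i)
      cell_chain(raw$snapshots[[i]], t = raw$times[i]))
  structure(list(times = raw$times, L = raw$L, N = raw$N, chains = chains,
                 final_chain = cell_chain(raw$x_final, t = raw$times[length(raw$times)]),
                 dt = dt),
            class = "chain_trajectory")
}

#' @export
print.chain_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<chain_trajectory> %d records over t in [%g, %g]; L: %g -> %g; N: %d -> %d\n",
              n, x$times[1], x$times[n], x$L[1], x$L[n], x$N[1], x$N[n]))
  invisible(x)
}

#' Simulate the cell-based model
#'
#' Forward-Euler integration of the overdamped chain, with the stochastic
#' division check applied after the mechanics update on every step. Given the
#' same seed the run is exactly reproducible.
#'
#' @param chain Initial [cell_chain()].
#' @param law A [force_law()].
#' @param plaw A [proliferation_law()], or `NULL` for movement only.
#' @param dt Time step (the reference cell-based runs use 0.001).
#' @param t_end Final time; the number of steps is `round(t_end / dt)`.
#' @param record_every Recording stride in steps; the initial and final
#'   states are always recorded.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @param path `"general"` or the specialised `"linear"` stencil.
#' @param snapshots Keep full chain snapshots at recorded times.
#' @return A `chain_trajectory`: recorded `times`, free-boundary positions
#'   `L`, cell counts `N`, optional `chains`, and `final_chain`.
#' @export
simulate_chain <- function(chain, law, plaw = NULL, dt = 1e-3, t_end,
                           record_every = 1L, seed = NULL,
                           path = c("general", "linear"), snapshots = FALSE) {
  path <- match.arg(path)
  if (path == "linear" && law$n != 1)
    stop("the linear path is only valid for force-law exponent n = 1", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (t_end < 0) stop("`t_end` must be non-negative", call. = FALSE)
  n_steps <- as.integer(round(t_end / dt))
  if (!is.null(seed)) set.seed(seed)
  if (n_steps == 0L)
    return(as_trajectory(list(times = chain$t, L = chain$x[chain$N + 1], N = chain$N,
                              x_final = chain$x,
                              snapshots = list(chain$x)), dt, snapshots))
  raw <- chain_run_cpp(chain$x, chain$t, law$k, law$a, law$n, law$eta,
                       path == "linear", plaw_family_code(plaw),
                       if (is.null(plaw)) 0 else plaw$beta,
                       if (is.null(plaw)) 1 else plaw$a_ref,
                       if (is.null(plaw)) 4 else plaw$shape,
                       if (!is.null(plaw) && plaw$family == "custom") plaw$rate_fn else NULL,
                       dt, n_steps, as.integer(record_every), snapshots)
  as_trajectory(raw, dt, snapshots)
}

#' Run the chain mechanics until the free boundary has relaxed
#'
#' Integrates (without proliferation) in growing stages until the leading
#' edge `L(t)` changes by less than `rel_tol` (relative) over the trailing
#' `window` fraction of the elapsed run, or until `t_max` is reached.
#'
#' @inheritParams simulate_chain
#' @param rel_tol Relative change in `L` below which the run counts as
#'   relaxed (default 0.01%).
#' @param window Trailing fraction of the run over which the change is
#'   measured.
#' @param t_max Hard cap on the simulated time.
#' @param t_first Duration of the first stage (doubled until relaxation).
#' @return A list with the relaxed `chain`, the elapsed time `t_end`,
#'   logical `relaxed`, and the coarse `times` / `L` series examined.
#' @export
simulate_to_relaxation <- function(chain, law, dt = 1e-3, rel_tol = 1e-4,
                                   window = 0.1, t_max = 2000, t_first = 25,
                                   path = c("general", "linear")) {
  path <- match.arg(path)
  times <- chain$t
  L <- chain$x[chain$N + 1]
  t0 <- chain$t
  total <- 0
  stage <- t_first
  relaxed <- FALSE
  repeat {
    stage <- min(stage, t_max - total)
    record_every <- max(1L, as.integer(round(stage / dt / 50)))
    traj <- simulate_chain(chain, law, NULL, dt, stage, record_every, path = path)
    chain <- traj$final_chain
    times <- c(times, traj$times[-1])
    L <- c(L, traj$L[-1])
    total <- total + stage
    tail_idx <- times >= t0 + (1 - window) * total
    span <- max(L[tail_idx]) - min(L[tail_idx])
    if (span / L[length(L)] < rel_tol) {
      relaxed <- TRUE
      break
    }
    if (total >= t_max) break
    stage <- min(total, t_max - total)
  }
  list(chain = chain, t_end = total, relaxed = relaxed, times = times, L = L)
}

#' Ensemble of stochastic realisations
#'
#' Runs `n_realisations` independent realisations of the stochastic model;
#' realisation `r` uses seed `seed + r`, so any single member is
#' independently reproducible. Summarises the free-boundary position and
#' cell number by their per-time mean and standard deviation.
#'
#' @inheritParams simulate_chain
#' @param n_realisations Number of realisations, at least 1.
#' @return An `ensemble_summary` with `times`, `mean_L`, `std_L`, `mean_N`,
#'   `std_N` and `n_realisations`.
#' @export
run_ensemble <- function(chain, law, plaw, dt = 1e-3, t_end, record_every = 1L,
                         seed = 1L, n_realisations = 100L) {
  if (n_realisations < 1) stop("`n_realisations` must be at least 1", call. = FALSE)
  Ls <- NULL
  Ns <- NULL
  times <- NULL
  for (r in seq_len(n_realisations)) {
    traj <- simulate_chain(chain, law, plaw, dt, t_end, record_every,
                           seed = seed + r)
    if (is.null(times)) {
      times <- traj$times
      Ls <- matrix(NA_real_, n_realisations, length(times))
      Ns <- matrix(NA_real_, n_realisations, length(times))
    }
    Ls[r, ] <- traj$L
    Ns[r, ] <- traj$N
  }
  sd0 <- function(m) {
    s <- apply(m, 2, sd)
    s[is.na(s)] <- 0
    s
  }
  structure(list(times = times,
                 mean_L = colMeans(Ls), std_L = sd0(Ls),
                 mean_N = colMeans(Ns), std_N = sd0(Ns),
                 n_realisations = n_realisations),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<ensemble_summary> %d realisations, %d records over t in [%g, %g]; mean N: %g -> %g\n",
              x$n_realisations, n, x$times[1], x$times[n], x$mean_N[1], x$mean_N[n]))
  invisible(x)
}
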