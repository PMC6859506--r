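#' Compare discrete and continuum leading edges
#'
#' Aligns a cell-based trajectory (or ensemble summary) with a continuum
#' solution at the trajectory's recorded times (the continuum series is
#' interpolated linearly in time) and reports the relative sup-norm
#' discrepancies of the free-boundary position and of the cell number:
#' `error_L = max_t |L_disc - L_pde| / L_disc`, and analogously `error_N`.
#'
#' @param traj A `chain_trajectory` or `ensemble_summary`.
#' @param pde A `pde_solution`.
#' @return A `comparison_result` with the aligned series and the two scalar
#'   discrepancies.
#' @export
compare_leading_edge <- function(traj, pde) {
  if (inherits(traj, "ensemble_summary")) {
    times <- traj$times; L_d <- traj$mean_L; N_d <- traj$mean_N
  } else if (inherits(traj, "chain_trajectory")) {
    times <- traj$times; L_d <- traj$L; N_d <- as.numeric(traj$N)
  } else stop("`traj` must be a chain_trajectory or ensemble_summary", call. = FALSE)
  tol <- 1e-9 * max(abs(times), 1)
  if (min(times) < min(pde$times) - tol || max(times) > max(pde$times) + tol)
    stop("recording times of the two models do not overlap: cannot align series",
         call. = FALSE)
  L_p <- approx(pde$times, pde$L, xout = times, rule = 2)$y
  N_p <- approx(pde$times, pde$N, xout = times, rule = 2)$y
  structure(list(times = times, L_discrete = L_d, L_pde = L_p,
                 N_discrete = N_d, N_pde = N_p,
                 error_L = max(abs(L_d - L_p) / L_d),
                 error_N = max(abs(N_d - N_p) / N_d)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d aligned times; error_L = %.3g, error_N = %.3g\n",
              length(x$times), x$error_L, x$error_N))
  invisible(x)
}

#' Fitted order of convergence
#'
#' Least-squares slope magnitude of `log(error)` against `log(N)`.
#'
#' @param N Cell numbers (at least 3 values).
#' @param errors Positive discrepancies, one per `N`.
#' @export
fit_convergence_order <- function(N, errors) {
  if (length(N) < 3 || length(errors) != length(N))
    stop("need at least 3 (N, error) pairs", call. = FALSE)
  if (any(errors <= 0)) stop("errors must be positive for a log-log fit", call. = FALSE)
  abs(unname(coef(lm(log(errors) ~ log(N)))[2]))
}

# shared runner: one matched discrete/PDE comparison without proliferation.
# Returns the trajectory, the two solutions requested and their comparisons.
run_matched_comparison <- function(N, law, domain_length = 30, dt = 1e-3,
                                   cfg = pde_config(), t_max = 400,
                                   n_records = 100, legacy_too = TRUE,
                                   relax_tol = 1e-3) {
  chain0 <- compressed_chain(N, domain_length)
  relax <- simulate_to_relaxation(chain0, law, dt = dt, rel_tol = relax_tol,
                                  t_max = t_max)
  # round the horizon so that both recorders hit the same 100 times
  t_end <- max(ceiling(relax$t_end / (n_records * dt)) * n_records * dt,
               n_records * dt)
  stride_d <- as.integer(round(t_end / dt / n_records))
  traj <- simulate_chain(chain0, law, NULL, dt, t_end, stride_d)
  pde_new <- solve_pde(chain0, law = law, cfg = cfg, t_end = t_end)
  out <- list(t_end = t_end, trajectory = traj, pde = pde_new,
              comparison = compare_leading_edge(traj, pde_new))
  if (legacy_too) {
    pde_legacy <- solve_pde(chain0, law = law, cfg = cfg, t_end = t_end,
                            legacy_boundary = TRUE)
    out$pde_legacy <- pde_legacy
    out$comparison_legacy <- compare_leading_edge(traj, pde_legacy)
  }
  out
}

#' Convergence of the continuum model in the cell number
#'
#' For each `N`, runs the non-proliferative linear-law chain initialised
#' with `N` equal cells in `(0, domain_length)` with the scalings
#' `a = a_times_N / N` and `alpha = alpha_over_N2 * N^2` (which keep the
#' macroscopic problem fixed as `N` grows), solves the continuum model with
#' both the mass-conserving and the legacy `q = 1/a` boundary conditions,
#' and measures the relative sup-norm leading-edge discrepancy. The fitted
#' log-log slope of error against `N` estimates the order of accuracy of the
#' coarse-grained model.
#'
#' @param N_values Cell numbers (at least 3, each at least 10).
#' @param domain_length Initial domain length.
#' @param a_times_N Product `a * N`, held fixed across `N`.
#' @param alpha_over_N2 Ratio `alpha / N^2`, held fixed across `N`.
#' @param dt Discrete time step.
#' @param cfg A [pde_config()] used for all continuum runs.
#' @param t_max Cap on the per-`N` relaxation horizon.
#' @param n_records Number of comparison times.
#' @return A list with a per-`N` `table` (errors under both boundary
#'   conditions) and the fitted orders `order_new` and `order_legacy`.
#' @export
convergence_study <- function(N_values = c(15, 30, 60, 120), domain_length = 30,
                              a_times_N = 45, alpha_over_N2 = 15 / 45^2,
                              dt = 1e-3, cfg = pde_config(M = 401L, dt = 2e-3),
                              t_max = 400, n_records = 100) {
  if (length(N_values) < 3) stop("need at least 3 values of N", call. = FALSE)
  if (any(N_values < 10)) stop("each N must be at least 10", call. = FALSE)
  err_new <- err_legacy <- t_ends <- numeric(length(N_values))
  for (i in seq_along(N_values)) {
    N <- N_values[i]
    law <- force_law(k = alpha_over_N2 * N^2, a = a_times_N / N, n = 1, eta = 1)
    run <- run_matched_comparison(N, law, domain_length, dt, cfg, t_max, n_records)
    err_new[i] <- run$comparison$error_L
    err_legacy[i] <- run$comparison_legacy$error_L
    t_ends[i] <- run$t_end
  }
  list(table = data.frame(N = N_values, error_new_bc = err_new,
                          error_legacy_bc = err_legacy, t_end = t_ends),
       order_new = fit_convergence_order(N_values, err_new),
       order_legacy = fit_convergence_order(N_values, err_legacy))
}

#' Run a named computational experiment
#'
#' Reproduces the package's standard experiment designs:
#'
#' * `"fig2"`: linear force law, `N` cells (default 15) with `a = 45/N`,
#'   `alpha = 15 (N/45)^2`, uniformly compressed in `(0, 30)`; one discrete
#'   run and two continuum runs (mass-conserving and legacy boundary
#'   conditions) with leading-edge comparisons.
#' * `"fig4"`: the three force laws (`n` = 1, 3/2, 3) with `N = 45`,
#'   `a = 1`, `alpha = 15`; discrete versus continuum comparison per law.
#' * `"fig7_fig8"`: the 3 x 3 grid of force laws by proliferation families
#'   (constant, length-proportional, target-length) with `N = 30`, `a = 1`,
#'   `alpha = 15`, `beta = 0.001`; ensemble summaries versus the
#'   proliferative continuum model, with the fraction of recorded times at
#'   which the continuum prediction lies within one ensemble standard
#'   deviation of the ensemble mean.
#'
#' @param name One of `"fig2"`, `"fig4"`, `"fig7_fig8"`.
#' @param out_dir Optional directory; when given, per-run CSV files,
#'   `comparison.csv`, `config.json` and `summary.json` are written there.
#' @param N Cell number for `"fig2"`.
#' @param n_realisations Ensemble size for `"fig7_fig8"`.
#' @param t_end Time horizon for `"fig7_fig8"` ensembles.
#' @param seed Root seed for ensembles.
#' @param cfg A [pde_config()].
#' @param dt Discrete time step.
#' @param t_max Cap on relaxation horizons.
#' @return A result bundle (list); the components depend on the experiment.
#' @export
run_figure_experiment <- function(name = c("fig2", "fig4", "fig7_fig8"),
                                  out_dir = NULL, N = 15, n_realisations = 100L,
                                  t_end = 300, seed = 1L, cfg = pde_config(),
                                  dt = 1e-3, t_max = 400) {
  name <- match.arg(name)
  config <- list(experiment = name, N = N, n_realisations = n_realisations,
                 t_end = t_end, seed = seed, dt = dt, t_max = t_max,
                 M = cfg$M, pde_dt = cfg$dt, picard_tol = cfg$picard_tol)
  result <- switch(name,
    fig2 = {
      law <- force_law(k = 15 * (N / 45)^2, a = 45 / N, n = 1, eta = 1)
      run_matched_comparison(N, law, 30, dt, cfg, t_max)
    },
    fig4 = {
      runs <- lapply(c(1, 3 / 2, 3), function(n) {
        law <- force_law(k = 15, a = 1, n = n, eta = 1)
        run_matched_comparison(45, law, 30, dt, cfg, t_max, legacy_too = FALSE)
      })
      names(runs) <- c("linear", "hertz", "cubic")
      runs
    },
    fig7_fig8 = {
      chain0 <- compressed_chain(30, 30)
      grid <- expand.grid(force = c("linear", "hertz", "cubic"),
                          prolif = c("constant", "length_proportional", "target_length"),
                          stringsAsFactors = FALSE)
      cells <- lapply(seq_len(nrow(grid)), function(i) {
        law <- force_law(k = 15, a = 1, n = grid$force[i], eta = 1)
        plaw <- proliferation_law(grid$prolif[i], beta = 1e-3, a_ref = 1)
        stride <- max(1L, as.integer(round(t_end / dt / 100)))
        ens <- run_ensemble(chain0, law, plaw, dt, t_end, stride,
                            seed = seed, n_realisations = n_realisations)
        pde <- solve_pde(chain0, law = law, plaw = plaw, cfg = cfg, t_end = t_end)
        cmp <- compare_leading_edge(ens, pde)
        list(force = grid$force[i], prolif = grid$prolif[i],
             ensemble = ens, pde = pde, comparison = cmp,
             bracket_L = mean(abs(cmp$L_pde - ens$mean_L) <= ens$std_L + 1e-9),
             bracket_N = mean(abs(cmp$N_pde - ens$mean_N) <= ens$std_N + 1e-9))
      })
      names(cells) <- paste(grid$force, grid$prolif, sep = ".")
      cells
    })
  if (!is.null(out_dir)) write_experiment_outputs(name, config, result, out_dir)
  result
}
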