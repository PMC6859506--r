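#' Write a data frame as CSV with full precision
#'
#' Deterministic column order and a fixed float format (17 significant
#' digits), so files written from identical runs diff cleanly.
#'
#' @param df A data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

required_field <- function(config, path) {
  node <- config
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[key]]))
      stop("config is missing required field `", path, "`", call. = FALSE)
    node <- node[[key]]
  }
  node
}

#' Load a run configuration
#'
#' Reads a YAML run configuration and validates its schema. A configuration
#' names the `model` to run (`discrete`, `pde`, `compare`, `ensemble` or
#' `convergence`) and carries a `force` block (`k`, `a`, `n`, `eta`), a
#' `proliferation` block (`family`, `beta`, `a_ref`, `shape`), an `initial`
#' block (`n_cells`, `domain_length`), a `numerics` block (`dt`, `t_end`,
#' `record_every`, `M`, `pde_dt`, `picard_tol`, `picard_max`), a `seed` and
#' an optional `output` directory. Missing optional fields take the
#' package defaults; missing required fields are reported by path.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param config A raw configuration list.
#' @export
validate_run_config <- function(config) {
  model <- required_field(config, "model")
  if (!model %in% c("discrete", "pde", "compare", "ensemble", "convergence"))
    stop("config field `model` must be one of discrete, pde, compare, ensemble, convergence",
         call. = FALSE)
  defaults <- list(
    force = list(k = 1, a = 1, n = 1, eta = 1),
    proliferation = list(family = "none", beta = 0, a_ref = 1, shape = 4),
    initial = list(n_cells = 15, domain_length = 30),
    numerics = list(dt = 1e-3, t_end = 100, record_every = 100L, M = 201L,
                    pde_dt = 0.01, picard_tol = 1e-10, picard_max = 600L),
    seed = 1L, n_realisations = 100L, output = NULL)
  for (block in c("force", "proliferation", "initial", "numerics"))
    config[[block]] <- modifyList(defaults[[block]],
                                  if (is.null(config[[block]])) list() else config[[block]])
  for (key in c("seed", "n_realisations"))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  for (key in c("force.k", "force.a", "force.n", "force.eta",
                "proliferation.a_ref", "initial.n_cells", "initial.domain_length",
                "numerics.dt", "numerics.t_end", "numerics.pde_dt")) {
    v <- required_field(config, key)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field `", key, "` must be a single positive number", call. = FALSE)
  }
  if (config$proliferation$beta < 0)
    stop("config field `proliferation.beta` must be non-negative", call. = FALSE)
  structure(config, class = "run_config")
}

#' @rdname load_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_law <- function(config)
  force_law(k = config$force$k, a = config$force$a, n = config$force$n,
            eta = config$force$eta)

config_plaw <- function(config) {
  p <- config$proliferation
  if (p$family == "none") NULL
  else proliferation_law(p$family, beta = p$beta, a_ref = p$a_ref, shape = p$shape)
}

config_chain <- function(config)
  compressed_chain(config$initial$n_cells, config$initial$domain_length)

config_pde_cfg <- function(config)
  pde_config(M = config$numerics$M, dt = config$numerics$pde_dt,
             picard_tol = config$numerics$picard_tol,
             picard_max = config$numerics$picard_max)

#' Execute a run configuration
#'
#' Dispatches to the simulation entry point named by `config$model` and
#' returns its result. If the configuration has an `output` directory, the
#' result and a `meta.json` capturing the full parameterisation are written
#' there.
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @return The model result (class depends on the model).
#' @export
run_model <- function(config) {
  config <- validate_run_config(config)
  law <- config_law(config)
  plaw <- config_plaw(config)
  num <- config$numerics
  set.seed(config$seed)
  result <- switch(config$model,
    discrete = simulate_chain(config_chain(config), law, plaw, num$dt, num$t_end,
                              num$record_every, seed = config$seed),
    pde = solve_pde(config_chain(config), law = law, plaw = plaw,
                    cfg = config_pde_cfg(config), t_end = num$t_end),
    compare = {
      stride <- max(1L, as.integer(round(num$t_end / num$dt / 100)))
      traj <- simulate_chain(config_chain(config), law, plaw, num$dt, num$t_end,
                             stride, seed = config$seed)
      pde <- solve_pde(config_chain(config), law = law, plaw = plaw,
                       cfg = config_pde_cfg(config), t_end = num$t_end)
      list(trajectory = traj, pde = pde,
           comparison = compare_leading_edge(traj, pde))
    },
    ensemble = run_ensemble(config_chain(config), law, plaw, num$dt, num$t_end,
                            num$record_every, seed = config$seed,
                            n_realisations = config$n_realisations),
    convergence = convergence_study(cfg = config_pde_cfg(config),
                                    dt = num$dt, t_max = num$t_end))
  if (!is.null(config$output)) write_run_outputs(result, config$output, config)
  result
}

result_frames <- function(result) {
  if (inherits(result, "chain_trajectory"))
    return(list(trajectory = data.frame(time = result$times, L = result$L,
                                        N = result$N)))
  if (inherits(result, "pde_solution")) {
    frames <- list(pde_summary = data.frame(
      time = result$times, L = result$L, N = result$N,
      boundary_residual = result$boundary_residual,
      picard_iters = result$picard_iters))
    fs <- result$final_state
    frames$pde_final_state <- data.frame(X = fs$X, Gamma = fs$Gamma, q = fs$q)
    return(frames)
  }
  if (inherits(result, "ensemble_summary"))
    return(list(ensemble = data.frame(time = result$times,
                                      mean_L = result$mean_L, std_L = result$std_L,
                                      mean_N = result$mean_N, std_N = result$std_N)))
  if (inherits(result, "comparison_result"))
    return(list(comparison = data.frame(time = result$times,
                                        L_discrete = result$L_discrete,
                                        L_pde = result$L_pde,
                                        N_discrete = result$N_discrete,
                                        N_pde = result$N_pde)))
  if (is.list(result)) {
    frames <- list()
    for (nm in names(result))
      for (sub in names(fr <- result_frames(result[[nm]])))
        frames[[paste(nm, sub, sep = "_")]] <- fr[[sub]]
    return(frames)
  }
  list()
}

#' Write a result to a directory
#'
#' Writes the columnar series of a result as full-precision CSV files plus a
#' `meta.json` with the complete parameterisation (so the run can be exactly
#' regenerated), and returns the manifest of files written.
#'
#' @param result A result object (trajectory, solution, ensemble summary,
#'   comparison, or a named list of these).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` stored in `meta.json`.
#' @return Character vector of files written.
#' @export
write_run_outputs <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- result_frames(result)
  manifest <- character()
  for (nm in names(frames)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    write_csv17(frames[[nm]], path)
    manifest <- c(manifest, path)
  }
  meta <- list(package = "epichain",
               version = as.character(utils::packageVersion("epichain")),
               written = format(Sys.time(), tz = "UTC"),
               config = if (is.null(config)) NULL else unclass(config))
  meta_path <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  c(manifest, meta_path)
}

write_experiment_outputs <- function(name, config, result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summary <- list(experiment = name)
  if (name == "fig2") {
    write_run_outputs(list(discrete = result$trajectory, pde_new = result$pde,
                           pde_legacy = result$pde_legacy), out_dir)
    write_csv17(data.frame(time = result$comparison$times,
                           L_discrete = result$comparison$L_discrete,
                           L_pde_new = result$comparison$L_pde,
                           L_pde_legacy = result$comparison_legacy$L_pde),
                file.path(out_dir, "comparison.csv"))
    summary$error_L_new_bc <- result$comparison$error_L
    summary$error_L_legacy_bc <- result$comparison_legacy$error_L
  } else {
    rows <- lapply(names(result), function(nm) {
      cell <- result[[nm]]
      write_run_outputs(cell[intersect(names(cell),
                                       c("trajectory", "ensemble", "pde", "comparison"))],
                        file.path(out_dir, nm))
      data.frame(cell = nm, error_L = cell$comparison$error_L,
                 error_N = cell$comparison$error_N,
                 bracket_L = if (is.null(cell$bracket_L)) NA_real_ else cell$bracket_L,
                 bracket_N = if (is.null(cell$bracket_N)) NA_real_ else cell$bracket_N)
    })
    write_csv17(do.call(rbind, rows), file.path(out_dir, "comparison.csv"))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Merge command-line flag overrides into a run configuration
#'
#' Flags take precedence over config-file values. A force law may be named
#' (`force` = linear/hertz/cubic) or given by exponent (`n`), but not both:
#' mixing the two is a precedence conflict and is rejected.
#'
#' @param config A `run_config` (or raw list).
#' @param flags Named list of overrides: `force`, `n`, `k`, `a`, `eta`,
#'   `prolif`, `beta`, `a_ref`, `n_cells`, `length`, `dt`, `t_end`, `M`,
#'   `pde_dt`, `seed`, `n_realisations`, `output`.
#' @return The merged, validated `run_config`.
#' @export
merge_config_flags <- function(config, flags) {
  flags <- flags[!vapply(flags, is.null, logical(1))]
  if (!is.null(flags[["force"]]) && !is.null(flags[["n"]]))
    stop("conflicting flags: give either a named force law (`force`) or an exponent (`n`), not both",
         call. = FALSE)
  if (!is.null(flags[["force"]]))
    flags[["n"]] <- switch(flags[["force"]], linear = 1, hertz = 3 / 2, cubic = 3,
                      stop("unknown force law name: ", flags[["force"]], call. = FALSE))
  config <- unclass(config)
  put <- function(cfg, block, key, val) {
    if (!is.null(val)) cfg[[block]][[key]] <- val
    cfg
  }
  config <- put(config, "force", "n", flags[["n"]])
  config <- put(config, "force", "k", flags[["k"]])
  config <- put(config, "force", "a", flags[["a"]])
  config <- put(config, "force", "eta", flags[["eta"]])
  config <- put(config, "proliferation", "family", flags[["prolif"]])
  config <- put(config, "proliferation", "beta", flags[["beta"]])
  config <- put(config, "proliferation", "a_ref", flags[["a_ref"]])
  config <- put(config, "initial", "n_cells", flags[["n_cells"]])
  config <- put(config, "initial", "domain_length", flags[["length"]])
  config <- put(config, "numerics", "dt", flags[["dt"]])
  config <- put(config, "numerics", "t_end", flags[["t_end"]])
  config <- put(config, "numerics", "M", flags$M)
  config <- put(config, "numerics", "pde_dt", flags[["pde_dt"]])
  for (key in c("seed", "n_realisations", "output"))
    if (!is.null(flags[[key]])) config[[key]] <- flags[[key]]
  validate_run_config(config)
}
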