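#' Run a configured experiment and write its results
#'
#' A single entry point for the package's paper-style experiments, driven
#' by a run configuration (a named list, or a YAML file readable with
#' [read_run_config()]).  Results are written as tidy CSV plus a JSON
#' manifest recording the full configuration, the package version, a
#' schema version and the seed, so a run can be reproduced exactly.
#'
#' Supported experiments (field `experiment`):
#' * `"hopfield-bs"`: basin stability of the four Hopfield equilibria at
#'   one delay.  Fields: `tau`, `basis`, `n`, `alpha`, `T`, `seed`.
#' * `"convergence-scan"`: [convergence_scan()] over `n_grid`/`alpha_grid`
#'   for the Hopfield model.  Fields: `tau`, `bases`, `n_grid`,
#'   `alpha_grid`, `tolerance`, `T`, `seed`.
#' * `"bs-vs-tau"`: [hopfield_bs_vs_tau()].  Fields: `tau_grid`, `bases`,
#'   `n`, `alpha`, `T`, `seed`.
#' * `"msf"`: [msf_scan()] for the delay-coupled Rossler network.
#'   Fields: `eps_grid` (or `eps_min`/`eps_max`/`eps_by`), `tau`,
#'   `component`.
#' * `"network-sweep"`: [network_bs_sweep()].  Fields: `p_grid`, `N`, `k`,
#'   `tau`, `realizations`, `n_sigma`, `T`, `alpha`, `seed`.
#' * `"fixture"`: [estimate_bs()] on a named fixture.  Fields: `fixture`,
#'   `basis`, `n`, `alpha`, `T`, `seed`.
#'
#' Every stochastic experiment requires an explicit `seed`; a missing or
#' invalid field aborts with a message naming it.
#'
#' @param config named list or path to a YAML configuration file.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the result.
#' @return invisibly, a list with the result object, the tidy results
#'   table and the paths written.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  exp_names <- c("hopfield-bs", "convergence-scan", "bs-vs-tau", "msf",
                 "network-sweep", "fixture")
  if (is.null(config$experiment) || !config$experiment %in% exp_names) {
    abort(sprintf("config field `experiment` must be one of: %s.",
                  paste(exp_names, collapse = ", ")))
  }
  need_seed <- config$experiment != "msf"
  if (need_seed &&
      (is.null(config$seed) || !is.numeric(config$seed))) {
    abort("config field `seed` is required for stochastic experiments.")
  }
  cfg <- function(field, default = NULL) {
    v <- config[[field]] %||% default
    if (is.null(v)) abort(sprintf("config field `%s` is required.", field))
    v
  }

  result <- switch(config$experiment,
    "hopfield-bs" = {
      sys <- hopfield_system(tau = cfg("tau", 2))
      att <- hopfield_attractors(sys)
      plan <- sample_plan(cfg("basis", "trigonometric"), n = cfg("n", 20),
                          alpha = cfg("alpha", 6), T = cfg("T", 1000),
                          seed = config$seed)
      estimate_bs(sys, att, plan)
    },
    "convergence-scan" = {
      sys <- hopfield_system(tau = cfg("tau", 2))
      convergence_scan(sys, hopfield_attractors(sys),
                       bases = cfg("bases", c("trigonometric", "legendre",
                                              "bernstein")),
                       n_grid = cfg("n_grid", seq(2, 24, by = 2)),
                       alpha_grid = cfg("alpha_grid", 6),
                       tolerance = cfg("tolerance", 0.02),
                       T = cfg("T", 2000), seed = config$seed)
    },
    "bs-vs-tau" = {
      hopfield_bs_vs_tau(tau_grid = cfg("tau_grid", seq(0.5, 4, by = 0.5)),
                         bases = cfg("bases", c("trigonometric", "legendre",
                                                "bernstein")),
                         n = cfg("n", 20), alpha = cfg("alpha", 6),
                         T = cfg("T", 1000), seed = config$seed)
    },
    "msf" = {
      eg <- config$eps_grid %||%
        seq(cfg("eps_min", 0), cfg("eps_max", 6), by = cfg("eps_by", 0.25))
      msf_scan(eg, tau = cfg("tau", 0.4),
               component = cfg("component", "x"))
    },
    "network-sweep" = {
      network_bs_sweep(p_grid = cfg("p_grid", c(0, 0.05, 0.1, 0.3, 1)),
                       N = cfg("N", 30), k = cfg("k", 6),
                       tau = cfg("tau", 0.4),
                       realizations = cfg("realizations", 5),
                       n_sigma = cfg("n_sigma", 10), T = cfg("T", 200),
                       alpha = cfg("alpha", 1), seed = config$seed)
    },
    "fixture" = {
      fx <- fixture_system(cfg("fixture", "bistable-scalar"))
      if (is.null(fx$system)) {
        abort(sprintf("fixture `%s` has no sampleable system.", config$fixture))
      }
      plan <- sample_plan(cfg("basis", "trigonometric"), n = cfg("n", 5),
                          alpha = cfg("alpha", 2), T = cfg("T", 500),
                          seed = config$seed)
      estimate_bs(fx$system, fx$attractors, plan,
                  t_end = cfg("t_end", 150), settle = cfg("settle", 100))
    })

  table <- if (inherits(result, "bs_estimate")) tidy(result)
    else if (inherits(result, "bs_convergence")) result$grid
    else if (inherits(result, "msf_result")) tidy(result)
    else if (inherits(result, "bs_sweep")) tibble::as_tibble(result)
    else tibble::as_tibble(result)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(config$experiment, "-results.csv"))
    utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
    manifest <- list(
      schema = "delaybasin/run-manifest/1",
      package_version = as.character(utils::packageVersion("delaybasin")),
      experiment = config$experiment,
      config = config,
      written = csv)
    mpath <- file.path(out_dir, paste0(config$experiment, "-manifest.json"))
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(results = csv, manifest = mpath)
  }
  invisible(list(result = result, table = table, paths = paths))
}

#' Read or write a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file `%s` not found.", path))
  cfg <- yaml::read_yaml(path)
  # hand-written YAML: unquoted keys `n`/`y` are YAML-1.1 booleans
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  names(cfg)[names(cfg) == "TRUE"] <- "y"
  cfg
}

#' @rdname read_run_config
#' @param config named configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
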