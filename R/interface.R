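RUN_CONFIG_KEYS <- c("organism", "mode", "module", "generations",
                     "param", "grid_min", "grid_max", "grid_n",
                     "balance_with", "response", "case", "n", "horizon",
                     "dt", "seed", "tuning", "out_prefix")

#' Validated run configuration
#'
#' Collects everything one run of the simulator needs — organism, growth
#' regime, the module to execute and its numeric options — and validates it
#' up front, before any computation. Unknown keys are rejected so that typos
#' in config files fail loudly.
#'
#' @param config A named list (e.g. parsed from YAML via
#'   [read_run_config()]) or individual arguments via `...`.
#' @param ... Individual settings overriding `config`: `organism` ("yeast",
#'   "mammalian", or a fixture path), `mode` ("rich", "poor", "quiescent"),
#'   `module` ("simulate", "calibrate", "scan", "gradient", "population"),
#'   `generations`, `param`, `grid_min`/`grid_max`/`grid_n`, `balance_with`,
#'   `response`, `case`, `n`, `horizon`, `dt`, `seed`, `tuning`,
#'   `out_prefix`.
#' @return A list of class `"run_config"`.
#' @examples
#' run_config(organism = "yeast", mode = "rich", module = "simulate",
#'            generations = 8)
#' @export
run_config <- function(config = list(), ...) {
  cfg <- utils::modifyList(config, list(...))
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(organism = "yeast", mode = "rich", module = "simulate",
                   generations = 8, grid_n = 25, case = "none", n = 200,
                   dt = 0.02, seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$organism %in% c("yeast", "mammalian") && !file.exists(cfg$organism))
    stop("organism must be 'yeast', 'mammalian', or a fixture path, got: ",
         cfg$organism)
  cfg$mode <- match.arg(cfg$mode, c("rich", "poor", "quiescent"))
  cfg$module <- match.arg(cfg$module,
                          c("simulate", "calibrate", "scan", "gradient",
                            "population"))
  if (cfg$module == "population" && cfg$mode == "quiescent")
    stop("population simulation supports rich and poor regimes only")
  if (cfg$module == "scan" && is.null(cfg$param))
    stop("scan module requires 'param'")
  stopifnot(cfg$generations >= 1, cfg$n >= 1, cfg$dt > 0)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML config file.
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

provenance_header <- function(cfg, params) {
  c(paste0("cngrowth ", as.character(utils::packageVersion("cngrowth"))),
    paste0("seed: ", cfg$seed),
    paste0("organism: ", cfg$organism, "  mode: ", cfg$mode,
           "  module: ", cfg$module),
    paste0("params: ",
           paste(sprintf("%s=%g", PARAM_NAMES,
                         unlist(params[PARAM_NAMES])), collapse = " ")))
}

#' Write a data frame as CSV with a provenance header
#'
#' Output files embed the full parameter set, the seed and the package
#' version as `#`-prefixed comment lines, so every artifact is traceable and
#' the header round-trips through [utils::read.csv()] with `comment.char =
#' "#"`.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param header Character vector of header lines (without the `# `).
#' @return `path`, invisibly.
#' @export
write_csv_provenance <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Execute a configured run
#'
#' Dispatches a validated [run_config()] to the corresponding module and
#' writes its artifacts (CSV time series / ensembles, JSON summaries) under
#' `out_prefix`. Partial outputs are removed if the run fails.
#'
#' @param cfg A [run_config()].
#' @param out_prefix Path prefix for artifacts; overrides `cfg$out_prefix`.
#'   `NULL` suppresses file output (results are only returned).
#' @return Invisibly, a list with the module result and the paths written.
#' @export
run_analysis <- function(cfg, out_prefix = cfg$out_prefix) {
  stopifnot(inherits(cfg, "run_config"))
  org <- organism_params(cfg$organism)
  mode <- org$modes[[cfg$mode]]
  set.seed(cfg$seed)
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  emit_csv <- function(df, suffix) {
    if (is.null(out_prefix)) return()
    path <- paste0(out_prefix, suffix, ".csv")
    write_csv_provenance(df, path, provenance_header(cfg, org$params))
    written <<- c(written, path)
  }
  emit_json <- function(x, suffix) {
    if (is.null(out_prefix)) return()
    path <- paste0(out_prefix, suffix, ".json")
    x$provenance <- as.list(provenance_header(cfg, org$params))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, path)
  }
  result <- tryCatch(switch(
    cfg$module,
    simulate = {
      horizon <- cfg$horizon %||%
        if (cfg$mode == "quiescent" && org$organism == "mammalian") 2000
        else if (cfg$mode == "quiescent") 200 else 100
      if (cfg$mode == "quiescent") {
        ss <- quiescent_steady_state(org$state, org$params, mode,
                                     horizon = horizon)
        emit_json(list(steady_state = as.list(unclass(ss$state)),
                       volume = ss$volume, cn = ss$cn,
                       converged = ss$converged), "_steady")
        ss
      } else {
        traj <- simulate_generations(org$state, org$params, mode,
                                     n_generations = cfg$generations,
                                     gen_horizon = horizon)
        cn <- cn_ratio(traj)
        lam <- fit_growth_rate(traj, require_cycles = FALSE)
        emit_csv(traj$data, "_trajectory")
        emit_json(list(lambda = lam, doubling_time = log(2) / lam,
                       cn_steady = cn$steady, cn_flag = cn$steady_flag,
                       cn_min = cn$cycle_min, cn_max = cn$cycle_max),
                  "_summary")
        list(trajectory = traj, lambda = lam, cn = cn)
      }
    },
    calibrate = {
      rep <- calibrate(if (file.exists(cfg$organism)) "yeast" else cfg$organism)
      if (!is.null(out_prefix)) {
        path <- paste0(out_prefix, "_params.yaml")
        write_calibration(rep, path)
        written <- c(written, path)
      }
      rep
    },
    scan = {
      base <- baseline_value(org$params, mode, cfg$param)
      grid <- if (!is.null(cfg$grid_min))
        exp(seq(log(cfg$grid_min), log(cfg$grid_max),
                length.out = cfg$grid_n))
      else scan_grid(base, n = cfg$grid_n)
      sc <- scan_parameter(cfg$param, grid, org$state, org$params, mode,
                           balance_with = cfg$balance_with,
                           n_generations = cfg$generations)
      emit_csv(as.data.frame(sc), "_scan")
      sc
    },
    gradient = {
      gr <- normalized_gradient(org$state, org$params, mode,
                                response = cfg$response)
      emit_json(list(response = gr$response, mode = gr$mode,
                     gradient = as.list(gr$gradient),
                     signs = as.list(gr$signs)), "_gradient")
      gr
    },
    population = {
      res <- run_population(cfg$organism, cfg$mode, cfg$case,
                            n = cfg$n, t_final = cfg$horizon %||% 20,
                            dt = cfg$dt, seed = cfg$seed)
      snap <- data.frame(res$ensemble$states,
                         age = res$ensemble$age,
                         lineage = res$ensemble$lineage)
      emit_csv(snap, "_ensemble")
      emit_json(list(n_cells = res$summary$n_cells,
                     n_divisions = res$summary$n_divisions,
                     slope = res$summary$slope,
                     lin_rss = res$summary$lin_rss,
                     quad_rss = res$summary$quad_rss,
                     division_noise_sd = res$summary$division_noise_sd),
                "_summary")
      res
    }), error = function(e) { cleanup(); stop(e) })
  invisible(list(result = result, files = written))
}
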