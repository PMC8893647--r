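# parameters scanned / differentiated by default; degradation coefficients
# are tied across compartments (d1 = d1C = d1N etc.), matching how the model
# is analyzed.
SCAN_PARAMS <- c("s1", "s2", "s3", "t1", "t2", "t3", "t4", "t5",
                 "d1", "d2", "d3")

set_scan_param <- function(params, mode, name, value) {
  if (name %in% c("d1", "d2", "d3")) {
    params[[paste0(name, "C")]] <- value
    params[[paste0(name, "N")]] <- value
  } else if (name %in% PARAM_NAMES) {
    params[[name]] <- value
  } else stop("unknown parameter: ", name)
  list(params = params, mode = mode)
}

# map a scan-parameter name to its baseline value under a mode (quiescent
# overrides take precedence for s3 / t1 / d)
baseline_value <- function(params, mode, name) {
  if (mode$regime == "quiescent") {
    if (name == "s3") return(mode$s3)
    if (name == "t1") return(mode$t1_bar)
    if (name %in% c("d1", "d2", "d3")) return(mode$d)
  }
  if (mode$regime == "poor" && name == "t1") return(mode$t1_bar)
  if (name %in% c("d1", "d2", "d3")) return(params[[paste0(name, "C")]])
  params[[name]]
}

set_mode_aware <- function(params, mode, name, value) {
  if (mode$regime != "rich" && name == "t1") {
    mode$t1_bar <- value
    return(list(params = params, mode = mode))
  }
  if (mode$regime == "quiescent") {
    if (name == "s3") { mode$s3 <- value; return(list(params = params, mode = mode)) }
    if (name %in% c("d1", "d2", "d3")) {
      mode$d <- value; return(list(params = params, mode = mode))
    }
  }
  set_scan_param(params, mode, name, value)
}

simulate_response <- function(state, params, mode, n_generations = 8,
                              discard = 3, gen_horizon = 100,
                              quiescent_horizon = 200) {
  if (mode$regime == "quiescent") {
    ss <- withCallingHandlers(
      quiescent_steady_state(state, params, mode, horizon = quiescent_horizon),
      warning = function(w) invokeRestart("muffleWarning"))
    return(list(lambda = 0, cn = ss$cn, volume = ss$volume,
                rp_r = (ss$state[["RP_C"]] + ss$state[["RP_N"]]) /
                  (ss$state[["R_C"]] + ss$state[["R_N"]]),
                converged = ss$converged))
  }
  traj <- withCallingHandlers(
    simulate_generations(state, params, mode, n_generations = n_generations,
                         gen_horizon = gen_horizon,
                         record_dt = gen_horizon / 500),
    warning = function(w) invokeRestart("muffleWarning"))
  lam <- fit_growth_rate(traj, discard_cycles = discard,
                         require_cycles = FALSE)
  cn <- cn_ratio(traj)
  df <- traj$data
  div_times <- traj$divisions$time
  nd <- length(div_times)
  keep <- if (nd >= 2) df$time > div_times[nd - 1] else
    df$time >= stats::median(df$time)
  rp_r <- mean((df$RP_C[keep] + df$RP_N[keep]) /
                 (df$R_C[keep] + df$R_N[keep]))
  list(lambda = lam, cn = cn$steady, volume = mean(df$V_cell[keep]),
       rp_r = rp_r, converged = traj$complete && nd >= discard + 2)
}

#' Parameter scan of growth rate and C/N ratio
#'
#' Re-simulates the model over a grid of one parameter (or a 2-D grid of two
#' parameters, e.g. the `t4`-`t5` plane) and records the fitted growth rate
#' and steady C/N ratio at every point. Shrinking cells report a negative
#' growth rate rather than being clamped. A constrained scan holds the sum
#' of the scanned parameter and `balance_with` fixed at its baseline (used
#' for the `s1 + s2` budget trade-off).
#'
#' @param param Parameter name, or a character vector of two names for a 2-D
#'   scan. Degradation pairs are addressed as `"d1"`, `"d2"`, `"d3"`.
#' @param grid Numeric vector of values (1-D), or a named list of two
#'   vectors (2-D).
#' @param state,params,mode Baseline model (see [organism_params()]).
#' @param balance_with Optional parameter name that absorbs changes so that
#'   `param + balance_with` stays at its baseline sum (1-D scans only).
#' @param n_generations,discard,gen_horizon Simulation controls passed to
#'   [simulate_generations()].
#' @return A data.frame of class `"scan_result"`: one row per grid point
#'   with the parameter value(s), `lambda`, `cn`, `rp_r`, `converged`.
#' @examples
#' \donttest{
#' org <- organism_params("yeast")
#' sc <- scan_parameter("t1", c(200, 400, 800), org$state, org$params,
#'                      org$modes$rich, n_generations = 6)
#' sc$lambda
#' }
#' @export
scan_parameter <- function(param, grid, state, params,
                           mode = growth_mode("rich"),
                           balance_with = NULL,
                           n_generations = 8, discard = 3,
                           gen_horizon = 100) {
  if (length(param) == 2) {
    stopifnot(is.list(grid), length(grid) == 2)
    pts <- expand.grid(grid[[1]], grid[[2]])
    names(pts) <- param
  } else {
    grid <- sort(unique(grid))
    pts <- data.frame(grid)
    names(pts) <- param
  }
  base_sum <- if (!is.null(balance_with))
    baseline_value(params, mode, param) +
      baseline_value(params, mode, balance_with)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    pm <- list(params = params, mode = mode)
    for (nm in names(pts)) pm <- set_mode_aware(pm$params, pm$mode, nm, pts[i, nm])
    if (!is.null(balance_with))
      pm <- set_mode_aware(pm$params, pm$mode, balance_with,
                           base_sum - pts[i, param])
    out <- tryCatch(
      simulate_response(state, pm$params, pm$mode,
                        n_generations = n_generations, discard = discard,
                        gen_horizon = gen_horizon),
      error = function(e) list(lambda = NA_real_, cn = NA_real_,
                               volume = NA_real_, rp_r = NA_real_,
                               converged = FALSE))
    data.frame(lambda = out$lambda, cn = out$cn, volume = out$volume,
               rp_r = out$rp_r, converged = out$converged)
  })
  out <- cbind(pts, do.call(rbind, res))
  class(out) <- c("scan_result", "data.frame")
  attr(out, "param") <- param
  attr(out, "mode") <- mode$regime
  out
}

#' Logarithmic default scan grid
#'
#' @param center Baseline parameter value.
#' @param span Multiplicative half-range (default 10: grid spans
#'   `center/span` to `center*span`).
#' @param n Number of points.
#' @return Numeric vector, strictly increasing.
#' @export
scan_grid <- function(center, span = 10, n = 25) {
  exp(seq(log(center / span), log(center * span), length.out = n))
}

#' Normalized sensitivity gradient of a growth response
#'
#' Computes the gradient of a response (growth rate, C/N ratio, or quiescent
#' steady volume) with respect to the model parameters normalized by their
#' baseline values (`s_bar = s / s0`), by central finite differences with
#' relative step `rel_step`, and scales the resulting vector to unit
#' Euclidean length. The signed components say whether each parameter
#' increases or decreases the response; the unit normalization makes
#' profiles comparable across conditions (radar-chart form).
#'
#' In growing regimes the response defaults to `lambda`; in the quiescent
#' regime to the steady volume. The quiescent parameters `t1`, `s3` and the
#' single decay rate `d` refer to the mode's overrides.
#'
#' @param state,params,mode Baseline model.
#' @param response `"lambda"`, `"cn"`, or `"volume"`.
#' @param param_names Parameters to differentiate (default `SCAN_PARAMS`;
#'   quiescent mode collapses `d1`,`d2`,`d3` to one `d`).
#' @param rel_step Relative finite-difference step (default 0.01).
#' @param ... Passed to the underlying simulations.
#' @return A list of class `"gradient_profile"` with `gradient` (named, unit
#'   norm), `raw` (unnormalized derivatives), `signs`, `response`, `mode`.
#' @export
normalized_gradient <- function(state, params, mode = growth_mode("rich"),
                                response = NULL,
                                param_names = NULL,
                                rel_step = 0.01, ...) {
  if (is.null(response))
    response <- if (mode$regime == "quiescent") "volume" else "lambda"
  response <- match.arg(response, c("lambda", "cn", "volume"))
  if (is.null(param_names)) {
    param_names <- SCAN_PARAMS
    if (mode$regime == "quiescent")
      param_names <- c(setdiff(param_names, c("d1", "d2", "d3")), "d")
  }
  eval_at <- function(pm) {
    simulate_response(state, pm$params, pm$mode, ...)[[response]]
  }
  set_q <- function(name, value) {
    if (name == "d" && mode$regime == "quiescent") {
      m <- mode; m$d <- value
      list(params = params, mode = m)
    } else set_mode_aware(params, mode, name, value)
  }
  base_of <- function(name) {
    if (name == "d" && mode$regime == "quiescent") mode$d
    else baseline_value(params, mode, name)
  }
  raw <- vapply(param_names, function(nm) {
    p0 <- base_of(nm)
    f_hi <- eval_at(set_q(nm, p0 * (1 + rel_step)))
    f_lo <- eval_at(set_q(nm, p0 * (1 - rel_step)))
    (f_hi - f_lo) / (2 * rel_step)
  }, numeric(1))
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stop("zero gradient: response is flat at this step size")
  structure(list(gradient = raw / nrm, raw = raw, signs = sign(raw),
                 response = response, mode = mode$regime,
                 rel_step = rel_step),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("<gradient_profile> response:", x$response, " mode:", x$mode, "\n")
  print(round(x$gradient, 4))
  invisible(x)
}

#' Growth rate as a function of the ribosomal-protein-to-ribosome ratio
#'
#' The free ribosomal-protein to mature-ribosome ratio RP/R (an indicator of
#' assembly imbalance, e.g. in aneuploidy) cannot be set directly; it is
#' tuned through a parameter that shifts the balance: the disassembly
#' coefficient `d3` (raises RP/R), the assembly coefficient `s3`, or the
#' import coefficient `t2` (both lower it). This scan records, for each
#' tuning value, the steady RP/R and the growth rate, giving the implied
#' RP/R-to-lambda curve.
#'
#' @param tuning One of `"d3"`, `"s3"`, `"t2"`.
#' @param grid Positive tuning-parameter values.
#' @param state,params,mode Baseline model.
#' @param ... Passed to [scan_parameter()].
#' @return A `"scan_result"` data.frame ordered by RP/R, with columns for
#'   the tuning value, `rp_r`, `lambda`, `cn`, `converged`.
#' @export
rp_r_curve <- function(tuning = c("d3", "s3", "t2"), grid, state, params,
                       mode = growth_mode("rich"), ...) {
  tuning <- match.arg(tuning)
  stopifnot(all(grid > 0))
  sc <- scan_parameter(tuning, grid, state, params, mode, ...)
  sc[order(sc$rp_r), , drop = FALSE]
}
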