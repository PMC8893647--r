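#' Simulate a dividing single-cell lineage
#'
#' Integrates the governing equations with an adaptive stiff-capable solver
#' (`deSolve::lsodar`, relative tolerance 1e-8, absolute 1e-10) and locates
#' division by root-finding on total cell volume: the cell divides when
#' `V_C + V_N` reaches twice its value at birth, whereupon every component is
#' halved exactly. Quiescent-mode runs integrate to `gen_horizon` without
#' division (the volume never doubles).
#'
#' @param state Initial [cell_state()].
#' @param params A [kinetic_params()].
#' @param mode A [growth_mode()].
#' @param n_generations Number of division cycles to simulate (growing
#'   regimes).
#' @param gen_horizon Maximum duration of a single generation (h). A growing
#'   run that fails to double within the horizon stops with a warning.
#' @param record_dt Output grid spacing (h); defaults to `gen_horizon/2000`.
#' @return A list of class `"growth_trajectory"`:
#'   * `data`: data.frame with `time`, the seven counts, `V_C`, `V_N`,
#'     `V_cell`, `cn` (= `V_cell / V_N`), `generation`;
#'   * `divisions`: data.frame of division events (`time`, `volume_pre`) plus
#'     matrices `state_pre`, `state_post`;
#'   * `params`, `mode`, `complete` (FALSE when the horizon was exceeded).
#' @examples
#' \donttest{
#' org <- organism_params("yeast")
#' traj <- simulate_generations(org$state, org$params, org$modes$rich,
#'                              n_generations = 6)
#' fit_growth_rate(traj)
#' }
#' @export
simulate_generations <- function(state, params, mode = growth_mode("rich"),
                                 n_generations = 8, gen_horizon = 100,
                                 record_dt = NULL) {
  stopifnot(n_generations >= 1, gen_horizon > 0)
  validate_cell_state(state)
  v0 <- compartment_volumes(state, params, require_positive = TRUE)
  if (is.null(record_dt)) record_dt <- gen_horizon / 2000
  parms <- list(params = params, mode = mode)

  if (mode$regime == "quiescent") {
    times <- seq(0, gen_horizon, by = record_dt)
    out <- deSolve::lsoda(unclass(state), times, desolve_rhs, parms,
                          rtol = 1e-8, atol = 1e-10)
    return(new_trajectory(list(cbind(out, generation = 1)),
                          divisions = NULL, params = params, mode = mode,
                          complete = TRUE))
  }

  segs <- vector("list", n_generations)
  div_time <- numeric(0); div_vol <- numeric(0)
  pre <- post <- NULL
  y <- unclass(state); t0 <- 0; complete <- TRUE
  for (g in seq_len(n_generations)) {
    v_birth <- sum(compartment_volumes(y, params, require_positive = TRUE))
    root <- function(t, yy, pp)
      sum(compartment_volumes(yy, pp$params)) - 2 * v_birth
    times <- seq(t0, t0 + gen_horizon, by = record_dt)
    out <- deSolve::lsodar(y, times, desolve_rhs, parms,
                           rootfunc = root, rtol = 1e-8, atol = 1e-10)
    if (any(out[, STATE_NAMES] < -1e-9))
      stop("negative state encountered in generation ", g)
    # drop the duplicated segment-start row for generations after the first
    segs[[g]] <- cbind(out[if (g == 1) TRUE else -1, , drop = FALSE],
                       generation = g)
    if (is.null(attr(out, "troot"))) {
      warning("volume did not double within gen_horizon = ", gen_horizon,
              " h (generation ", g, "); stopping early")
      complete <- FALSE
      segs <- segs[seq_len(g)]
      break
    }
    last <- out[nrow(out), ]
    y_pre <- last[STATE_NAMES]
    div_time <- c(div_time, last[["time"]])
    div_vol <- c(div_vol, sum(compartment_volumes(y_pre, params)))
    pre <- rbind(pre, y_pre)
    y <- y_pre / 2
    post <- rbind(post, y)
    t0 <- last[["time"]]
  }
  if (!is.null(pre)) { rownames(pre) <- NULL; rownames(post) <- NULL }
  divisions <- if (length(div_time))
    list(events = data.frame(time = div_time, volume_pre = div_vol),
         state_pre = pre, state_post = post)
  new_trajectory(segs, divisions, params, mode, complete)
}

new_trajectory <- function(segs, divisions, params, mode, complete) {
  m <- do.call(rbind, segs)
  df <- as.data.frame(m)
  V_C <- (df$P_C + df$R_C + df$RP_C) / params$r1
  V_N <- (df$P_N + df$R_N + df$RP_N) / params$r2
  df$V_C <- V_C; df$V_N <- V_N; df$V_cell <- V_C + V_N
  df$cn <- df$V_cell / df$V_N
  structure(list(data = df,
                 divisions = divisions$events,
                 state_pre = divisions$state_pre,
                 state_post = divisions$state_post,
                 params = params, mode = mode, complete = complete),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  nd <- if (is.null(x$divisions)) 0 else nrow(x$divisions)
  cat("<growth_trajectory> ", x$mode$regime, " regime, ",
      nrow(x$data), " points over ", round(max(x$data$time), 3), " h, ",
      nd, " division(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.growth_trajectory <- function(x, ...) x$data

n_divisions_before <- function(t, div_times) {
  if (is.null(div_times) || !length(div_times)) return(numeric(length(t)))
  findInterval(t, div_times, left.open = TRUE)
}

#' Exponential growth rate from a trajectory
#'
#' Least-squares slope of log total cell volume versus time. Division
#' discontinuities are removed by adding `log(2)` per completed division
#' (division halves the volume exactly), which concatenates the per-cycle
#' log-increments into one continuous line. The first `discard_cycles`
#' generations are dropped as transient.
#'
#' @param traj A [simulate_generations()] result, or any object with a
#'   `data$time` / `data$V_cell` series and optional `divisions`.
#' @param discard_cycles Number of initial generations to discard.
#' @param require_cycles If `TRUE` (default), error unless at least two
#'   retained cycles are available; scans set this to `FALSE` to fit whatever
#'   tail exists (e.g. shrinking cells that never divide).
#' @return Growth rate lambda (1/h).
#' @export
fit_growth_rate <- function(traj, discard_cycles = 3, require_cycles = TRUE) {
  df <- traj$data
  if (any(df$V_cell <= 0)) stop("non-positive cell volume in trajectory")
  div_times <- traj$divisions$time
  n_div <- length(div_times)
  if (n_div >= discard_cycles + 2) {
    t_start <- div_times[discard_cycles]
  } else if (require_cycles) {
    stop("need at least ", discard_cycles + 2, " divisions for a fit after ",
         "discarding ", discard_cycles, " cycles; got ", n_div)
  } else {
    # fallback for non-dividing or slowly dividing runs: fit the final half
    t_start <- stats::median(df$time)
  }
  keep <- df$time >= t_start
  t <- df$time[keep]
  logv <- log(df$V_cell[keep]) +
    n_divisions_before(t, div_times) * log(2)
  unname(stats::coef(stats::lm(logv ~ t))[2])
}

#' Cell-to-nucleus volume ratio series and steady value
#'
#' Returns the C/N ratio `V_cell / V_N` over time together with the
#' steady-state summary: the mean over the final complete cycle, a
#' convergence flag (relative drift of the cycle mean below `drift_tol` per
#' hour), and the final-cycle minimum and maximum (informative in the
#' poor-nutrient regime, where the ratio oscillates within each cycle).
#'
#' @param traj A [simulate_generations()] result.
#' @param drift_tol Relative drift tolerance (per hour) for the steady flag.
#' @return List with `series` (data.frame `time`, `cn`), `steady`,
#'   `steady_flag`, `cycle_min`, `cycle_max`.
#' @export
cn_ratio <- function(traj, drift_tol = 1e-4) {
  df <- traj$data
  if (any(df$V_N <= 0)) stop("zero nuclear volume in trajectory")
  div_times <- traj$divisions$time
  n_div <- length(div_times)
  if (n_div >= 2) {
    last <- df$time > div_times[n_div - 1] & df$time <= div_times[n_div]
    prev <- if (n_div >= 3)
      df$time > div_times[n_div - 2] & df$time <= div_times[n_div - 1]
    else NULL
  } else {
    last <- df$time >= stats::median(df$time)
    prev <- NULL
  }
  steady <- mean(df$cn[last])
  if (!is.null(prev) && any(prev)) {
    cycle_len <- diff(div_times[(n_div - 1):n_div])
    drift <- abs(steady - mean(df$cn[prev])) / steady / cycle_len
  } else {
    fit <- stats::lm(df$cn[last] ~ df$time[last])
    drift <- abs(stats::coef(fit)[2]) / steady
  }
  list(series = data.frame(time = df$time, cn = df$cn),
       steady = steady, steady_flag = unname(drift < drift_tol),
       cycle_min = min(df$cn[last]), cycle_max = max(df$cn[last]))
}

#' Quiescent steady state
#'
#' Integrates the quiescent-regime equations until the state stops changing
#' (relative derivative norm below `tol` per hour) or the horizon is reached,
#' and summarizes the fixed point.
#'
#' @param state Initial [cell_state()].
#' @param params A [kinetic_params()].
#' @param mode A quiescent [growth_mode()].
#' @param horizon Maximum integration time (h); 200 is ample for yeast-scale
#'   kinetics, use ~2000 for mammalian-scale.
#' @param tol Convergence tolerance on `max |dx/dt| / x` (1/h).
#' @return List with `state` (the fixed point), `V_C`, `V_N`, `volume`,
#'   `cn`, `converged`, `time`.
#' @examples
#' \donttest{
#' org <- organism_params("yeast")
#' quiescent_steady_state(org$state, org$params, org$modes$quiescent)
#' }
#' @export
quiescent_steady_state <- function(state, params, mode,
                                   horizon = 200, tol = 1e-6) {
  if (mode$regime != "quiescent") stop("mode must be quiescent")
  parms <- list(params = params, mode = mode)
  y <- unclass(state)
  chunk <- horizon / 20
  t_now <- 0; converged <- FALSE
  while (t_now < horizon) {
    out <- deSolve::lsoda(y, c(t_now, t_now + chunk), desolve_rhs, parms,
                          rtol = 1e-10, atol = 1e-12)
    y <- out[nrow(out), STATE_NAMES]
    t_now <- t_now + chunk
    rel <- abs(growth_rhs(y, params, mode)) / pmax(abs(y), 1e-12)
    if (max(rel) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("quiescent state not converged within horizon = ", horizon, " h")
  v <- compartment_volumes(y, params)
  list(state = as_cell_state(y), V_C = v[["V_C"]], V_N = v[["V_N"]],
       volume = sum(v), cn = sum(v) / v[["V_N"]],
       converged = converged, time = t_now)
}
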