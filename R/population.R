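# ---- division rule ---------------------------------------------------------

#' Division-volume distribution and hazard
#'
#' Stochastic division is driven by a division-volume distribution
#' `omega(V)`: the probability density of the volume at which a cell
#' divides. The corresponding hazard per unit of volume growth is
#' `k(V) = omega(V) / (1 - CDF_omega(V))`, so a cell that grows by `dV`
#' during a step divides with probability `1 - exp(-k(V) dV)`. The CDF is
#' computed once by trapezoidal quadrature on a cached grid.
#'
#' The default rule is a normal distribution centered at twice the newborn
#' cytoplasmic volume with a 10% coefficient of variation, truncated to
#' positive support: in the zero-width limit this reduces to deterministic
#' division at volume doubling.
#'
#' @param density A vectorized density function of volume (um^3), or `NULL`
#'   to use the truncated-normal default defined by `mean_volume` and `cv`.
#' @param support Numeric length-2 support of the density.
#' @param mean_volume Mean division volume for the default density.
#' @param cv Coefficient of variation for the default density.
#' @param sigma_div Partition-noise scale: the standard deviation of the
#'   volume difference between the two newborn cells relative to the
#'   dividing volume, `(V1 - V2)/V_div ~ N(0, sigma_div)`. A dividing cell
#'   splits into fractions `f` and `1 - f` with `f = 1/2 + delta`,
#'   `delta ~ N(0, sigma_div / 2)` resampled to keep `f` inside (0, 1).
#' @param n_grid Quadrature grid size.
#' @return A list of class `"division_rule"` with the cached grid, pdf, cdf
#'   and `sigma_div`.
#' @examples
#' rule <- division_rule(mean_volume = 60)
#' division_hazard(c(50, 60, 70), rule)
#' @export
division_rule <- function(density = NULL, support = NULL,
                          mean_volume = NULL, cv = 0.1,
                          sigma_div = 0.125, n_grid = 1024) {
  if (is.null(density)) {
    if (is.null(mean_volume))
      stop("either a density or mean_volume must be given")
    sd <- cv * mean_volume
    density <- function(v) stats::dnorm(v, mean_volume, sd)
    if (is.null(support))
      support <- c(max(0, mean_volume - 8 * sd), mean_volume + 8 * sd)
  }
  if (is.null(support)) stop("custom densities need an explicit support")
  stopifnot(length(support) == 2, support[1] < support[2], sigma_div >= 0)
  v <- seq(support[1], support[2], length.out = n_grid)
  pdf <- density(v)
  if (any(pdf < 0)) stop("density must be non-negative on its support")
  h <- diff(v)
  cdf <- c(0, cumsum((pdf[-1] + pdf[-n_grid]) / 2 * h))
  total <- cdf[n_grid]
  if (total <= 0) stop("density integrates to zero on the support")
  pdf <- pdf / total               # renormalize (e.g. truncation at 0)
  cdf <- cdf / total
  structure(list(grid = v, pdf = pdf, cdf = cdf, support = support,
                 sigma_div = sigma_div),
            class = "division_rule")
}

#' @rdname division_rule
#' @param V Volumes at which to evaluate the hazard (um^3).
#' @param rule A `division_rule`.
#' @param eps CDF proximity to 1 treated as the certain-division regime
#'   (hazard `Inf`).
#' @return `division_hazard()`: the hazard `k(V)` (per um^3 of growth);
#'   0 below the support, `Inf` where division is certain.
#' @export
division_hazard <- function(V, rule, eps = 1e-12) {
  k <- numeric(length(V))
  lo <- V < rule$support[1]
  hi <- V >= rule$support[2]
  mid <- !lo & !hi
  if (any(mid)) {
    p <- stats::approx(rule$grid, rule$pdf, V[mid])$y
    cf <- stats::approx(rule$grid, rule$cdf, V[mid])$y
    surv <- 1 - cf
    k[mid] <- ifelse(surv <= eps, Inf, p / surv)
  }
  k[hi] <- Inf
  k
}

#' Quantile-free CDF of a division rule
#' @keywords internal
division_cdf <- function(V, rule) {
  out <- numeric(length(V))
  out[V >= rule$support[2]] <- 1
  mid <- V > rule$support[1] & V < rule$support[2]
  out[mid] <- stats::approx(rule$grid, rule$cdf, V[mid])$y
  out
}

# ---- two-protein regulation ------------------------------------------------

#' Two-protein synthesis regulation
#'
#' Splits the non-ribosomal proteome into two species P1 and P2 with their
#' own synthesis coefficients, optionally coupled: each coefficient may be a
#' constant or an affine function `a + b * P` of the *other* species' count
#' (in 10^6 molecules). Effective coefficients are clamped at zero. With one
#' species the model reduces exactly to the base equations; transport and
#' degradation coefficients are shared, regulation acts on synthesis only.
#'
#' Presets (yeast values): `"equal"` (s11 = s12 = 77.5), `"unequal"`
#' (s11 = 65, s12 = 90), `"enhance"` (s12 = 6 P1), `"suppress"`
#' (s12 = 145 - 5 P1).
#'
#' @param case Preset name, or `"none"` for the single-protein base model.
#' @param s11 Synthesis coefficient of P1 (um^3/10^6 h), or affine spec
#'   `c(intercept, slope)` in P2.
#' @param s12 Synthesis coefficient of P2, or affine spec `c(intercept,
#'   slope)` in P1.
#' @return A list of class `"regulation_spec"`.
#' @export
regulation_spec <- function(case = c("none", "equal", "unequal",
                                     "enhance", "suppress"),
                            s11 = NULL, s12 = NULL) {
  case <- match.arg(case)
  preset <- switch(case,
                   none = list(s11 = NULL, s12 = NULL),
                   equal = list(s11 = 77.5, s12 = 77.5),
                   unequal = list(s11 = 65, s12 = 90),
                   enhance = list(s11 = 77.5, s12 = c(0, 6)),
                   suppress = list(s11 = 77.5, s12 = c(145, -5)))
  if (!is.null(s11)) preset$s11 <- s11
  if (!is.null(s12)) preset$s12 <- s12
  structure(list(case = case, two_species = case != "none",
                 s11 = preset$s11, s12 = preset$s12),
            class = "regulation_spec")
}

# evaluate an affine-or-constant coefficient spec against the partner count
eval_coef <- function(spec, partner) {
  if (length(spec) == 1) rep_len(spec, length(partner))
  else pmax(spec[1] + spec[2] * partner, 0)
}

# ---- vectorized derivatives over a population matrix ----------------------

POP_COLS <- c("A_C", "P1_C", "P2_C", "RP_C", "R_C", "P_N", "RP_N", "R_N")

# states: matrix with POP_COLS columns (P2_C all zero when single-species).
# Returns the Euler increment matrix for one dt. Non-ribosomal synthesis
# uses per-species coefficients; transport and degradation treat P1+P2 as
# one pool and are applied pro rata.
population_derivs <- function(states, params, mode, reg) {
  p <- params
  A <- states[, "A_C"]; P1 <- states[, "P1_C"]; P2 <- states[, "P2_C"]
  RP_C <- states[, "RP_C"]; R_C <- states[, "R_C"]
  P_N <- states[, "P_N"]; RP_N <- states[, "RP_N"]; R_N <- states[, "R_N"]
  P_C <- P1 + P2
  V_C <- (P_C + R_C + RP_C) / p$r1
  V_N <- (P_N + R_N + RP_N) / p$r2
  fC <- V_C / (V_C + V_N)
  if (reg$two_species) {
    s11 <- eval_coef(reg$s11, P2)
    s12 <- eval_coef(reg$s12, P1)
  } else {
    s11 <- rep_len(p$s1, length(A)); s12 <- 0
  }
  t1_bar <- if (mode$regime == "rich") p$t1 * P_C else mode$t1_bar
  s3 <- effective_s3(p, mode)
  trans <- A * R_C / V_C
  quiescent <- mode$regime == "quiescent"
  if (quiescent) {
    d <- mode$d
    degP_C <- d * P_C; degP_N <- d * P_N
    degRP_C <- d * RP_C; degRP_N <- d * RP_N
    disR_C <- d * R_C; disR_N <- d * R_N
  } else {
    degP_C <- p$d1C * P_C^2 / V_C
    degP_N <- p$d1N * P_N^2 / V_N
    degRP_C <- p$d2C * RP_C * P_C / V_C
    degRP_N <- p$d2N * RP_N * P_N / V_N
    disR_C <- p$d3C * R_C * P_C / V_C
    disR_N <- p$d3N * R_N * P_N / V_N
  }
  netP <- (p$t4 * P_C / V_C - p$t5 * P_N / V_N) * P_C
  share1 <- ifelse(P_C > 0, P1 / P_C, 0.5)
  dP1 <- s11 * trans / p$n1 - degP_C * share1 - netP * share1
  dP2 <- s12 * trans / p$n1 - degP_C * (1 - share1) - netP * (1 - share1)
  dA <- fC * (t1_bar + p$n1 * (degP_C + degP_N) +
                p$n2 * (degRP_C + degRP_N)) -
    (s11 + s12 + p$s2) * trans
  dRP_C <- p$n3 * disR_C + p$s2 * trans / p$n2 -
    p$t2 * RP_C * P_C / V_C - degRP_C
  dR_C <- p$t3 * R_N * P_C / V_N - disR_C
  dRP_N <- p$t2 * RP_C * P_C / V_C - s3 * RP_N - degRP_N + p$n3 * disR_N
  dR_N <- (s3 / p$n3) * RP_N - p$t3 * R_N * P_C / V_N - disR_N
  dP_N <- netP - degP_N
  cbind(A_C = dA, P1_C = dP1, P2_C = dP2, RP_C = dRP_C, R_C = dR_C,
        P_N = dP_N, RP_N = dRP_N, R_N = dR_N)
}

population_volumes <- function(states, params) {
  V_C <- (states[, "P1_C"] + states[, "P2_C"] + states[, "R_C"] +
            states[, "RP_C"]) / params$r1
  V_N <- (states[, "P_N"] + states[, "R_N"] + states[, "RP_N"]) / params$r2
  cbind(V_C = V_C, V_N = V_N)
}

# ---- ensemble --------------------------------------------------------------

#' Initialize a population ensemble
#'
#' Creates `n` cells whose states are the reference newborn state scaled by
#' independent Uniform(1, 2) factors — i.e. model variables evenly
#' distributed between one and two times the estimated initial conditions,
#' with a single shared factor per cell so each cell keeps the reference
#' composition. With a two-species regulation spec the non-ribosomal pool is
#' split equally between P1 and P2.
#'
#' @param n Number of cells.
#' @param state Reference newborn [cell_state()].
#' @param reg A [regulation_spec()].
#' @return A list of class `"population_ensemble"`: `states` (matrix, one
#'   row per cell), `age`, `lineage`, `time`, `total_scale` (subsampling
#'   correction factor for extensive totals), `divisions` (running count),
#'   `division_log` (data.frame of division events).
#' @export
init_population <- function(n, state, reg = regulation_spec("none")) {
  stopifnot(n >= 1)
  u <- stats::runif(n, 1, 2)
  base <- unclass(state)
  states <- matrix(0, n, length(POP_COLS),
                   dimnames = list(NULL, POP_COLS))
  split <- if (reg$two_species) 0.5 else 1
  for (i in seq_len(n)) {
    s <- base * u[i]
    states[i, ] <- c(s[["A_C"]], s[["P_C"]] * split,
                     s[["P_C"]] * (1 - split), s[["RP_C"]], s[["R_C"]],
                     s[["P_N"]], s[["RP_N"]], s[["R_N"]])
  }
  structure(list(states = states, age = numeric(n),
                 lineage = seq_len(n), time = 0, total_scale = 1,
                 divisions = 0L,
                 division_log = list(time = numeric(0),
                                     volume = numeric(0),
                                     delta = numeric(0))),
            class = "population_ensemble")
}

#' @export
print.population_ensemble <- function(x, ...) {
  cat("<population_ensemble> ", nrow(x$states), " cells at t = ",
      round(x$time, 3), " h; ", x$divisions, " divisions\n", sep = "")
  invisible(x)
}

#' Advance a population ensemble by one time step
#'
#' Each cell advances deterministically by an explicit Euler step of the
#' governing equations over `dt`; then each cell divides with probability
#' `1 - exp(-integral of k(V) dV)` over the cytoplasmic volume gained during
#' the step, where `k` is the hazard of `rule`. The integrated hazard is
#' evaluated exactly as the log-ratio of the survival function `1 - CDF`, so
#' the division-volume distribution converges to the configured `omega`
#' independent of `dt`. A dividing cell splits into
#' fractions `f = 1/2 + delta` and `1 - f`, with the newborn volume
#' difference `(V1 - V2)/V_div = 2 delta` drawn from `N(0, sigma_div)` and
#' resampled until `f` lies in (0, 1), applied identically to every
#' constituent; both daughters are retained.
#'
#' @param pop A [init_population()] ensemble.
#' @param params A [kinetic_params()].
#' @param mode A [growth_mode()].
#' @param rule A [division_rule()].
#' @param reg A [regulation_spec()].
#' @param dt Time step (h); 0.02 by convention.
#' @return The advanced `population_ensemble`.
#' @export
step_population <- function(pop, params, mode, rule,
                            reg = regulation_spec("none"), dt = 0.02) {
  stopifnot(dt > 0)
  st <- pop$states
  v_before <- population_volumes(st, params)[, "V_C"]
  st <- st + dt * population_derivs(st, params, mode, reg)
  if (any(st < 0)) {
    if (any(st < -1e-8)) stop("negative counts in population step")
    st[st < 0] <- 0
  }
  v_after <- population_volumes(st, params)[, "V_C"]
  # survival over the step's traversed volume: exp(-int k dV) equals the
  # ratio of survival functions S = 1 - CDF, which integrates the hazard
  # exactly over the increment (no quadrature error for finite dt)
  S_before <- 1 - division_cdf(v_before, rule)
  S_after <- 1 - division_cdf(v_after, rule)
  p_div <- ifelse(v_after > v_before & S_before > 0,
                  pmin(pmax(1 - S_after / S_before, 0), 1),
                  ifelse(S_before <= 0 & v_after > v_before, 1, 0))
  dividing <- which(stats::runif(nrow(st)) < p_div)
  if (length(dividing)) {
    deltas <- vapply(dividing, function(i) {
      repeat {
        delta <- stats::rnorm(1, 0, rule$sigma_div / 2)
        f <- 0.5 + delta
        if (f > 0 && f < 1) return(delta)
      }
    }, numeric(1))
    f <- 0.5 + deltas
    mothers <- st[dividing, , drop = FALSE]
    d1 <- mothers * f
    d2 <- mothers * (1 - f)
    st[dividing, ] <- d1
    st <- rbind(st, d2)
    pop$age[dividing] <- 0
    pop$age <- c(pop$age, numeric(length(dividing)))
    pop$lineage <- c(pop$lineage, pop$lineage[dividing])
    pop$divisions <- pop$divisions + length(dividing)
    pop$division_log$time <- c(pop$division_log$time,
                               rep(pop$time + dt, length(dividing)))
    # the division occurred somewhere within the step's volume traversal;
    # log the midpoint as the expected division volume
    pop$division_log$volume <- c(pop$division_log$volume,
                                 (v_before[dividing] + v_after[dividing]) / 2)
    # log the newborn volume-difference ratio (V1 - V2)/V_div = 2 delta
    pop$division_log$delta <- c(pop$division_log$delta, 2 * deltas)
  }
  keep <- setdiff(seq_along(pop$age), dividing)
  pop$age[keep] <- pop$age[keep] + dt
  pop$states <- st
  pop$time <- pop$time + dt
  pop
}

#' Run a stochastic population simulation
#'
#' Evolves an ensemble of cells under the deterministic growth equations
#' plus stochastic volume-triggered division, and summarizes the steady
#' proteome distribution. When the population exceeds `cap`, a uniform
#' random half is kept and the `total_scale` factor doubled so extensive
#' totals remain interpretable.
#'
#' @param organism Organism tag or fixture path for [organism_params()].
#' @param mode_name `"rich"` or `"poor"` (the regimes used for population
#'   distributions).
#' @param case Regulation preset for [regulation_spec()].
#' @param n Initial number of cells.
#' @param t_final Simulated time (h).
#' @param dt Euler step (h).
#' @param seed RNG seed (set once at the start).
#' @param cap Population size triggering subsampling.
#' @param rule Optional [division_rule()]; defaults to the truncated normal
#'   centered at twice the newborn cytoplasmic volume, `cv` 0.1,
#'   `sigma_div` 0.125.
#' @return A list of class `"population_result"`: the final `ensemble`,
#'   `summary` (see below), and the run configuration. `summary` contains
#'   cell volumes, P1/P2 counts, the P2-on-P1 linear regression slope, the
#'   residual sums of squares of the linear and quadratic fits, the
#'   division-noise standard deviation (sample sd of the newborn
#'   volume-difference ratio), the division-volume sample, and the
#'   time series of log total volume (`trace`).
#' @examples
#' \donttest{
#' res <- run_population(n = 50, t_final = 6, case = "equal", seed = 1)
#' res$summary$slope
#' }
#' @export
run_population <- function(organism = "yeast", mode_name = "rich",
                           case = "none", n = 200, t_final = 20,
                           dt = 0.02, seed = 1, cap = 2000, rule = NULL) {
  org <- organism_params(organism)
  mode <- org$modes[[match.arg(mode_name, c("rich", "poor"))]]
  reg <- regulation_spec(case)
  set.seed(seed)
  if (is.null(rule)) {
    v0 <- compartment_volumes(org$state, org$params)[["V_C"]]
    rule <- division_rule(mean_volume = 2 * v0)
  }
  pop <- init_population(n, org$state, reg)
  n_steps <- ceiling(t_final / dt)
  trace_t <- numeric(n_steps); trace_logv <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    pop <- step_population(pop, org$params, mode, rule, reg, dt)
    if (nrow(pop$states) > cap) {
      m <- nrow(pop$states)
      keep <- sample.int(m, ceiling(cap / 2))
      pop$total_scale <- pop$total_scale * m / length(keep)
      pop$states <- pop$states[keep, , drop = FALSE]
      pop$age <- pop$age[keep]
      pop$lineage <- pop$lineage[keep]
    }
    v <- population_volumes(pop$states, org$params)
    trace_t[s] <- pop$time
    trace_logv[s] <- log(sum(v) * pop$total_scale)
  }
  v <- population_volumes(pop$states, org$params)
  P1 <- pop$states[, "P1_C"]; P2 <- pop$states[, "P2_C"]
  slope <- lin_rss <- quad_rss <- NA_real_
  if (reg$two_species && stats::sd(P1) > 0) {
    fit_lin <- stats::lm(P2 ~ P1)
    fit_quad <- stats::lm(P2 ~ I(P1^2))
    slope <- unname(stats::coef(fit_lin)[2])
    lin_rss <- sum(stats::resid(fit_lin)^2)
    quad_rss <- sum(stats::resid(fit_quad)^2)
  }
  structure(list(
    ensemble = pop,
    summary = list(
      n_cells = nrow(pop$states),
      volumes = unname(rowSums(v)),
      P1 = P1, P2 = P2,
      slope = slope, lin_rss = lin_rss, quad_rss = quad_rss,
      n_divisions = pop$divisions,
      division_noise_sd = if (pop$divisions > 1)
        stats::sd(pop$division_log$delta) else NA_real_,
      division_volumes = pop$division_log$volume,
      division_times = pop$division_log$time,
      trace = data.frame(time = trace_t, log_total_volume = trace_logv)),
    config = list(organism = org$organism, mode = mode$regime, case = case,
                  n = n, t_final = t_final, dt = dt, seed = seed,
                  cap = cap)),
    class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result> ", x$config$organism, "/", x$config$mode,
      ", case ", x$config$case, ": ", x$summary$n_cells, " cells, ",
      x$summary$n_divisions, " divisions over ", x$config$t_final,
      " h\n", sep = "")
  invisible(x)
}
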