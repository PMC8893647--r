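zero_flux <- function() {
  x <- numeric(7)
  names(x) <- STATE_NAMES
  x
}

effective_s3 <- function(params, mode) {
  if (mode$regime == "quiescent") mode$s3 else params$s3
}

effective_uptake <- function(P_C, params, mode) {
  if (mode$regime == "rich") params$t1 * P_C else mode$t1_bar
}

#' Protein synthesis and ribosome assembly fluxes
#'
#' Translation is a sequential assembly: the production rate of a protein of
#' length `n` is proportional to the amino-acid concentration and to the
#' concentration of ribosomes occupying the final elongation step (a fraction
#' `1/n` of translating ribosomes). Hence
#' `dP_C/dt = s1 A_C R_C / (n1 V_C)` and
#' `dRP_C/dt = s2 A_C R_C / (n2 V_C)`, consuming amino acids at
#' `(s1 + s2) A_C R_C / V_C`. Ribosome assembly in the nucleus converts `n3`
#' ribosomal proteins per ribosome: `dR_N/dt = (s3/n3) RP_N`,
#' `dRP_N/dt = -s3 RP_N`.
#'
#' @param state A [cell_state()].
#' @param params A [kinetic_params()].
#' @param mode A [growth_mode()]; the quiescent regime substitutes its
#'   assembly override for `s3`.
#' @return Named numeric vector: the synthesis contribution to d(state)/dt
#'   (10^6 molecules/h).
#' @export
synthesis_fluxes <- function(state, params, mode = growth_mode("rich")) {
  f <- zero_flux()
  s3 <- effective_s3(params, mode)
  translation <- state[["A_C"]] * state[["R_C"]]
  if (translation > 0) {
    V_C <- compartment_volumes(state, params)[["V_C"]]
    if (V_C <= 0) stop("degenerate state: V_C = 0 with active translation")
    f[["P_C"]] <- params$s1 * translation / (params$n1 * V_C)
    f[["RP_C"]] <- params$s2 * translation / (params$n2 * V_C)
    f[["A_C"]] <- -(params$s1 + params$s2) * translation / V_C
  }
  f[["R_N"]] <- (s3 / params$n3) * state[["RP_N"]]
  f[["RP_N"]] <- -s3 * state[["RP_N"]]
  f
}

#' Import and nucleocytoplasmic transport fluxes
#'
#' Amino-acid import adds `V_C/(V_C+V_N) * t1_bar` to the cytoplasmic pool,
#' where the uptake `t1_bar` is `t1 * P_C` in the rich regime (transporter
#' abundance scales with the proteome) and a constant in poor/quiescent
#' conditions; the nuclear fraction of import is not tracked. Carrier-mediated
#' transport across the nuclear envelope scales with cargo concentration and
#' with `P_C` (carrier abundance): ribosomal proteins move inward at
#' `t2 RP_C P_C / V_C`, mature ribosomes outward at `t3 R_N P_C / V_N`, and
#' non-ribosomal protein exchanges with net inward flux
#' `(t4 P_C/V_C - t5 P_N/V_N) P_C`. Each transported species is conserved
#' across the envelope.
#'
#' @inheritParams synthesis_fluxes
#' @return Named numeric vector: the transport contribution to d(state)/dt.
#' @export
transport_fluxes <- function(state, params, mode = growth_mode("rich")) {
  f <- zero_flux()
  v <- compartment_volumes(state, params)
  V_C <- v[["V_C"]]; V_N <- v[["V_N"]]
  if (V_C <= 0 || V_N <= 0)
    stop("degenerate state: transport requires positive volumes")
  f[["A_C"]] <- V_C / (V_C + V_N) *
    effective_uptake(state[["P_C"]], params, mode)
  netP <- (params$t4 * state[["P_C"]] / V_C -
             params$t5 * state[["P_N"]] / V_N) * state[["P_C"]]
  f[["P_C"]] <- -netP
  f[["P_N"]] <- netP
  fRP <- params$t2 * state[["RP_C"]] * state[["P_C"]] / V_C
  f[["RP_C"]] <- -fRP
  f[["RP_N"]] <- fRP
  fR <- params$t3 * state[["R_N"]] * state[["P_C"]] / V_N
  f[["R_N"]] <- -fR
  f[["R_C"]] <- fR
  f
}

#' Degradation, disassembly and amino-acid recycling fluxes
#'
#' In growing regimes degradation is bimolecular (substrate meets a
#' degradation machinery whose abundance scales with the compartment's
#' non-ribosomal protein pool): e.g. `dP_C/dt = -d1C P_C^2 / V_C`. Ribosome
#' disassembly releases `n3` ribosomal proteins per particle, and degraded
#' protein is recycled into the cytoplasmic amino-acid pool, scaled by
#' `V_C/(V_C+V_N)` (the nuclear share of recycled amino acids is not
#' tracked). The quiescent regime replaces every bimolecular term with
#' first-order decay at rate `mode$d`, keeping the same stoichiometric
#' structure (disassembly still yields `n3` ribosomal proteins; amino acids
#' are still recycled).
#'
#' @inheritParams synthesis_fluxes
#' @return Named numeric vector: the degradation contribution to d(state)/dt.
#' @export
degradation_fluxes <- function(state, params, mode = growth_mode("rich")) {
  f <- zero_flux()
  v <- compartment_volumes(state, params)
  V_C <- v[["V_C"]]; V_N <- v[["V_N"]]
  n3 <- params$n3
  if (mode$regime == "quiescent") {
    d <- mode$d
    degP_C <- d * state[["P_C"]]
    degP_N <- d * state[["P_N"]]
    degRP_C <- d * state[["RP_C"]]
    degRP_N <- d * state[["RP_N"]]
    disR_C <- d * state[["R_C"]]
    disR_N <- d * state[["R_N"]]
  } else {
    if (V_C <= 0 || V_N <= 0)
      stop("degenerate state: degradation requires positive volumes")
    degP_C <- params$d1C * state[["P_C"]]^2 / V_C
    degP_N <- params$d1N * state[["P_N"]]^2 / V_N
    degRP_C <- params$d2C * state[["RP_C"]] * state[["P_C"]] / V_C
    degRP_N <- params$d2N * state[["RP_N"]] * state[["P_N"]] / V_N
    disR_C <- params$d3C * state[["R_C"]] * state[["P_C"]] / V_C
    disR_N <- params$d3N * state[["R_N"]] * state[["P_N"]] / V_N
  }
  f[["P_C"]] <- -degP_C
  f[["P_N"]] <- -degP_N
  f[["R_C"]] <- -disR_C
  f[["R_N"]] <- -disR_N
  f[["RP_C"]] <- n3 * disR_C - degRP_C
  f[["RP_N"]] <- n3 * disR_N - degRP_N
  cyto_frac <- if (V_C + V_N > 0) V_C / (V_C + V_N) else 0
  f[["A_C"]] <- cyto_frac *
    (params$n1 * (degP_C + degP_N) + params$n2 * (degRP_C + degRP_N))
  f
}

#' Right-hand side of the governing growth equations
#'
#' Time derivative of the full seven-component state: amino-acid import and
#' recycling minus translational consumption, protein synthesis, ribosome
#' assembly, nucleocytoplasmic transport, and degradation/disassembly. This
#' function transcribes the governing equations term by term; it is
#' numerically identical to the component-wise sum of [synthesis_fluxes()],
#' [transport_fluxes()] and [degradation_fluxes()].
#'
#' @inheritParams synthesis_fluxes
#' @return Named numeric vector d(state)/dt (10^6 molecules/h).
#' @examples
#' growth_rhs(yeast_state(), yeast_params(), growth_mode("rich"))
#' @export
growth_rhs <- function(state, params, mode = growth_mode("rich")) {
  p <- params
  A_C <- state[["A_C"]]; P_C <- state[["P_C"]]; RP_C <- state[["RP_C"]]
  R_C <- state[["R_C"]]; P_N <- state[["P_N"]]; RP_N <- state[["RP_N"]]
  R_N <- state[["R_N"]]
  V_C <- (P_C + R_C + RP_C) / p$r1
  V_N <- (P_N + R_N + RP_N) / p$r2
  total <- V_C + V_N
  if (total <= 0) {           # fully empty cell: every term vanishes
    if (all(state == 0)) return(zero_flux())
    stop("degenerate state: zero total volume with non-zero counts")
  }
  if (V_C <= 0 || V_N <= 0)
    stop("degenerate state: compartment volume is zero")
  fC <- V_C / total
  t1_bar <- effective_uptake(P_C, p, mode)
  s3 <- effective_s3(p, mode)
  quiescent <- mode$regime == "quiescent"

  if (quiescent) {
    d <- mode$d
    dA_C <- fC * (t1_bar +
                    p$n1 * (d * P_C + d * P_N) +
                    p$n2 * (d * RP_C + d * RP_N)) -
      (p$s1 + p$s2) * A_C * R_C / V_C
    dP_C <- p$s1 * A_C * R_C / (p$n1 * V_C) - d * P_C -
      (p$t4 * P_C / V_C - p$t5 * P_N / V_N) * P_C
    dR_C <- p$t3 * R_N * P_C / V_N - d * R_C
    dRP_C <- p$n3 * d * R_C + p$s2 * A_C * R_C / (p$n2 * V_C) -
      p$t2 * RP_C * P_C / V_C - d * RP_C
    dRP_N <- p$t2 * RP_C * P_C / V_C - s3 * RP_N - d * RP_N + p$n3 * d * R_N
    dR_N <- (s3 / p$n3) * RP_N - p$t3 * R_N * P_C / V_N - d * R_N
    dP_N <- (p$t4 * P_C / V_C - p$t5 * P_N / V_N) * P_C - d * P_N
  } else {
    dA_C <- fC * (t1_bar +
                    p$n1 * (p$d1C * P_C^2 / V_C + p$d1N * P_N^2 / V_N) +
                    p$n2 * (p$d2C * RP_C * P_C / V_C +
                              p$d2N * RP_N * P_N / V_N)) -
      (p$s1 + p$s2) * A_C * R_C / V_C
    dP_C <- p$s1 * A_C * R_C / (p$n1 * V_C) - p$d1C * P_C^2 / V_C -
      (p$t4 * P_C / V_C - p$t5 * P_N / V_N) * P_C
    dR_C <- p$t3 * R_N * P_C / V_N - p$d3C * R_C * P_C / V_C
    dRP_C <- p$n3 * p$d3C * R_C * P_C / V_C +
      p$s2 * A_C * R_C / (p$n2 * V_C) -
      p$t2 * RP_C * P_C / V_C - p$d2C * RP_C * P_C / V_C
    dRP_N <- p$t2 * RP_C * P_C / V_C - s3 * RP_N -
      p$d2N * RP_N * P_N / V_N + p$n3 * p$d3N * R_N * P_N / V_N
    dR_N <- (s3 / p$n3) * RP_N - p$t3 * R_N * P_C / V_N -
      p$d3N * R_N * P_N / V_N
    dP_N <- (p$t4 * P_C / V_C - p$t5 * P_N / V_N) * P_C -
      p$d1N * P_N^2 / V_N
  }
  out <- c(A_C = dA_C, P_C = dP_C, RP_C = dRP_C, R_C = dR_C,
           P_N = dP_N, RP_N = dRP_N, R_N = dR_N)
  if (any(!is.finite(out)))
    stop("non-finite derivative encountered; state: ",
         paste(sprintf("%s=%g", STATE_NAMES, state[STATE_NAMES]),
               collapse = ", "))
  out
}

# deSolve adapter
desolve_rhs <- function(t, y, parms) {
  list(growth_rhs(y, parms$params, parms$mode))
}
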