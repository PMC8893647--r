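# Shared fixtures: organism bundles are loaded once per test file.
yeast <- organism_params("yeast")
mam <- organism_params("mammalian")

random_states <- function(n, seed = 1, lo = 0.01, hi = 20) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    as_cell_state(stats::setNames(stats::runif(7, lo, hi),
                                  c("A_C", "P_C", "RP_C", "R_C",
                                    "P_N", "RP_N", "R_N")))
  })
}

# independently coded term-by-term derivative (transcribed directly from the
# governing equations, growing regimes), used as the oracle for growth_rhs
oracle_rhs_growing <- function(st, p, t1_bar) {
  A <- st[["A_C"]]; PC <- st[["P_C"]]; RPC <- st[["RP_C"]]; RC <- st[["R_C"]]
  PN <- st[["P_N"]]; RPN <- st[["RP_N"]]; RN <- st[["R_N"]]
  VC <- (PC + RC + RPC) / p$r1
  VN <- (PN + RN + RPN) / p$r2
  f <- VC / (VC + VN)
  c(A_C = f * (t1_bar + p$n1 * (p$d1C * PC^2 / VC + p$d1N * PN^2 / VN) +
                 p$n2 * (p$d2C * RPC * PC / VC + p$d2N * RPN * PN / VN)) -
      (p$s1 + p$s2) * A * RC / VC,
    P_C = p$s1 * A * RC / (p$n1 * VC) - p$d1C * PC^2 / VC -
      (p$t4 * PC / VC - p$t5 * PN / VN) * PC,
    RP_C = p$n3 * p$d3C * RC * PC / VC + p$s2 * A * RC / (p$n2 * VC) -
      p$t2 * RPC * PC / VC - p$d2C * RPC * PC / VC,
    R_C = p$t3 * RN * PC / VN - p$d3C * RC * PC / VC,
    P_N = (p$t4 * PC / VC - p$t5 * PN / VN) * PC - p$d1N * PN^2 / VN,
    RP_N = p$t2 * RPC * PC / VC - p$s3 * RPN - p$d2N * RPN * PN / VN +
      p$n3 * p$d3N * RN * PN / VN,
    R_N = (p$s3 / p$n3) * RPN - p$t3 * RN * PC / VN - p$d3N * RN * PN / VN)
}
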