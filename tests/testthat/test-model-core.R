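test_that("compartment volumes follow the count-to-volume law", {
  v <- compartment_volumes(yeast$state, yeast$params)
  expect_equal(v[["V_C"]], (15 + 0.135 + 1.35) / 0.6)   # ~27.475, tabulated 27
  expect_equal(v[["V_N"]], (1.65 + 0.015 + 0.15) / 0.6) # ~3.025, tabulated 3
  expect_equal(v[["V_C"]], 27.475, tolerance = 1e-12)
  expect_equal(v[["V_N"]], 3.025, tolerance = 1e-12)

  empty <- cell_state(A_C = 0, P_C = 0, RP_C = 0, R_C = 0,
                      P_N = 0, RP_N = 0, R_N = 0)
  expect_equal(unname(compartment_volumes(empty, yeast$params)), c(0, 0))
  expect_error(compartment_volumes(empty, yeast$params,
                                   require_positive = TRUE),
               "degenerate")
})

test_that("cell_state validates and orders its components", {
  expect_error(cell_state(-1, 1, 1, 1, 1, 1, 1), "non-negative")
  st <- as_cell_state(c(P_N = 1, RP_N = 2, R_N = 3,
                        A_C = 4, P_C = 5, RP_C = 6, R_C = 7))
  expect_equal(names(st), c("A_C", "P_C", "RP_C", "R_C",
                            "P_N", "RP_N", "R_N"))
  expect_error(as_cell_state(c(A_C = 1)), "must carry")
})

test_that("synthesis fluxes match the sequential-assembly arithmetic", {
  f <- synthesis_fluxes(yeast$state, yeast$params)
  V_C <- 27.475
  expect_equal(f[["P_C"]], 155 * 3200 * 0.135 / (400 * V_C))   # ~6.09
  expect_equal(f[["RP_C"]], 125 * 3200 * 0.135 / (400 * V_C))
  expect_equal(f[["R_N"]], 48 / 80 * 0.15)                     # 0.09
  expect_equal(f[["RP_N"]], -48 * 0.15)
  expect_equal(f[["A_C"]], -(155 + 125) * 3200 * 0.135 / V_C)
  expect_equal(f[["P_N"]], 0)
  expect_equal(f[["R_C"]], 0)

  # no ribosomes -> no translation
  st0 <- as_cell_state(replace(unclass(yeast$state), 4, 0))
  f0 <- synthesis_fluxes(st0, yeast$params)
  expect_equal(unname(f0[c("P_C", "RP_C", "A_C")]), c(0, 0, 0))
})

test_that("synthesis stoichiometry: amino acids consumed n-per-protein", {
  for (st in random_states(20, seed = 11)) {
    f <- synthesis_fluxes(st, yeast$params)
    expect_equal(-f[["A_C"]],
                 yeast$params$n1 * f[["P_C"]] + yeast$params$n2 * f[["RP_C"]],
                 tolerance = 1e-12)
  }
})

test_that("transport fluxes match the carrier-mediated forms and conserve cargo", {
  f <- transport_fluxes(yeast$state, yeast$params, growth_mode("rich"))
  expect_equal(f[["A_C"]], 27.475 / 30.5 * 400 * 15)  # ~5404
  netP <- (0.8 * 15 / 27.475 - 0.72 * 1.65 / 3.025) * 15
  expect_equal(f[["P_N"]], netP)
  expect_equal(f[["P_C"]], -netP)
  # with the tabulated alternative export coefficient 0.75
  p75 <- yeast$params; p75$t5 <- 0.75
  f75 <- transport_fluxes(yeast$state, p75, growth_mode("rich"))
  expect_equal(f75[["P_N"]], (0.8 * 15 / 27.475 - 0.75 * 1.65 / 3.025) * 15,
               tolerance = 1e-12)  # ~0.42

  for (st in random_states(25, seed = 2)) {
    for (mode in list(growth_mode("rich"),
                      growth_mode("poor", t1_bar = 2850))) {
      f <- transport_fluxes(st, yeast$params, mode)
      expect_equal(f[["P_C"]] + f[["P_N"]], 0)
      expect_equal(f[["RP_C"]] + f[["RP_N"]], 0)
      expect_equal(f[["R_C"]] + f[["R_N"]], 0)
    }
  }
})

test_that("poor-regime uptake is the constant t1_bar scaled by volume fraction", {
  mode <- growth_mode("poor", t1_bar = 2850)
  f <- transport_fluxes(yeast$state, yeast$params, mode)
  expect_equal(f[["A_C"]], 27.475 / 30.5 * 2850)
  d <- growth_rhs(yeast$state, yeast$params, mode) -
    growth_rhs(yeast$state, yeast$params, growth_mode("rich"))
  expect_equal(d[["A_C"]], 27.475 / 30.5 * (2850 - 400 * 15),
               tolerance = 1e-12)
})

test_that("degradation fluxes match the bimolecular forms", {
  f <- degradation_fluxes(yeast$state, yeast$params)
  V_C <- 27.475
  expect_equal(f[["P_C"]], -0.1 * 15^2 / V_C)        # ~-0.819
  # disassembly returns n3 ribosomal proteins per ribosome
  dis <- 80 * 0.1 * 0.135 * 15 / V_C                 # ~0.59
  expect_equal(f[["RP_C"]], dis - 0.1 * 1.35 * 15 / V_C)
  # recycled amino acids re-enter scaled by the cytoplasmic volume fraction
  V_N <- 3.025
  expect_equal(f[["A_C"]],
               V_C / (V_C + V_N) *
                 (400 * (0.1 * 15^2 / V_C + 0.1 * 1.65^2 / V_N) +
                    400 * (0.1 * 1.35 * 15 / V_C + 0.1 * 0.15 * 1.65 / V_N)))
})

test_that("quiescent degradation is first-order with the same stoichiometry", {
  mode <- growth_mode("quiescent", t1_bar = 2850, d = 0.8, s3 = 5)
  f <- degradation_fluxes(yeast$state, yeast$params, mode)
  expect_equal(f[["P_C"]], -0.8 * 15)     # -12
  expect_equal(f[["P_N"]], -0.8 * 1.65)
  expect_equal(f[["R_C"]], -0.8 * 0.135)  # ribosome decay, negative sign
  expect_equal(f[["RP_C"]], 80 * 0.8 * 0.135 - 0.8 * 1.35)
})

test_that("rhs equals the sum of the three flux families on random states", {
  modes <- list(growth_mode("rich"),
                growth_mode("poor", t1_bar = 2850),
                growth_mode("quiescent", t1_bar = 2850, d = 0.8, s3 = 5))
  for (st in random_states(100, seed = 3)) {
    for (mode in modes) {
      total <- synthesis_fluxes(st, yeast$params, mode) +
        transport_fluxes(st, yeast$params, mode) +
        degradation_fluxes(st, yeast$params, mode)
      r <- growth_rhs(st, yeast$params, mode)
      expect_equal(r, total, tolerance = 1e-12)
    }
  }
})

test_that("rhs matches an independently coded term-by-term transcription", {
  for (st in random_states(50, seed = 4)) {
    expect_equal(growth_rhs(st, yeast$params, growth_mode("rich")),
                 oracle_rhs_growing(st, yeast$params,
                                    yeast$params$t1 * st[["P_C"]]),
                 tolerance = 1e-12)
    expect_equal(growth_rhs(st, mam$params, growth_mode("poor",
                                                        t1_bar = 15000)),
                 oracle_rhs_growing(st, mam$params, 15000),
                 tolerance = 1e-12)
  }
})

test_that("all-zero state has zero derivative; positive orthant is invariant", {
  zero <- cell_state(0, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(growth_rhs(zero, yeast$params, growth_mode("rich"))),
               rep(0, 7))
  # any component at zero must have a non-negative derivative there
  for (st in random_states(30, seed = 5, lo = 0.05, hi = 5)) {
    for (j in 2:7) {  # keep volumes positive: zero one count at a time
      stj <- unclass(st); stj[j] <- 0
      v <- compartment_volumes(stj, yeast$params)
      if (any(v <= 0)) next
      d <- growth_rhs(as_cell_state(stj), yeast$params, growth_mode("rich"))
      expect_gte(d[[j]], 0)
    }
    st0 <- unclass(st); st0[1] <- 0   # empty amino-acid pool
    d <- growth_rhs(as_cell_state(st0), yeast$params, growth_mode("rich"))
    expect_gte(d[["A_C"]], 0)
  }
})

test_that("parameter and mode constructors validate their inputs", {
  expect_error(growth_mode("poor"), "t1_bar")
  expect_error(growth_mode("quiescent", t1_bar = 1), "d > 0")
  expect_error(do.call(kinetic_params,
                       replace(unclass(yeast$params), 1, -5)), "positive")
  expect_s3_class(yeast$modes$quiescent, "growth_mode")
  expect_equal(yeast$modes$quiescent$d, 0.8)
  expect_equal(mam$modes$quiescent$t1_bar, 15000)
})

test_that("parameter fixtures round-trip through write_params", {
  tmp <- tempfile(fileext = ".yaml")
  write_params(tmp, yeast$state, yeast$params, organism = "yeast",
               modes = list(poor_t1_bar = 2850, quiescent_t1_bar = 2850,
                            quiescent_d = 0.8, quiescent_s3 = 5),
               header = "round-trip check")
  back <- organism_params(tmp)
  expect_equal(unclass(back$state), unclass(yeast$state))
  expect_equal(unclass(back$params), unclass(yeast$params))
  expect_equal(back$modes$quiescent$s3, 5)
})
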