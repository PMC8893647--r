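# cngrowth

Coarse-grained simulation of eukaryotic cell growth and the cell-to-nucleus
volume (C/N) ratio.

Across cell types and growth conditions, nuclear volume is proportional to
cell volume. `cngrowth` implements a whole-cell dynamical model that
explains this correlation from the ribosome cycle and nucleocytoplasmic
transport. It tracks seven molecular pools — free amino acids (A_C),
non-ribosomal protein (P_C, P_N), free ribosomal protein (RP_C, RP_N) and
mature ribosomes (R_C, R_N) — coupled by translation
(dP_C/dt = s1·A_C·R_C/(n1·V_C)), nuclear ribosome assembly
(dR_N/dt = (s3/n3)·RP_N), carrier-mediated transport across the nuclear
envelope (coefficients t2–t5, all scaling with the cytoplasmic carrier pool
P_C), amino-acid import (t̄1 = t1·P_C when nutrients are rich, constant when
poor), and degradation/disassembly (coefficients d1–d3). Compartment
volumes follow from ion-and-water homeostasis as V_C = (P_C+R_C+RP_C)/r1,
V_N = (P_N+R_N+RP_N)/r2, so the model predicts volumes — and the C/N
ratio — from molecule counts.

Because all fluxes are first-order homogeneous in the state, balanced
exponential growth emerges in rich medium: every component grows at a
common rate λ and the C/N ratio is constant (≈10 for yeast, ≈5.5 for a
prototypical mammalian cell). A constant amino-acid supply gives linear
growth with a periodically fluctuating C/N ratio, and a quiescent regime
(first-order degradation, reduced ribosome assembly) gives a
constant-volume fixed point with a low C/N ratio (≈3 yeast, ≈2.2
mammalian).

The package provides:

* `organism_params()` — yeast and mammalian parameter fixtures (editable
  YAML, symbol names `s1`, `t4`, `d1C`, ... as in the model equations);
* `growth_rhs()`, `synthesis_fluxes()`, `transport_fluxes()`,
  `degradation_fluxes()` — the governing equations and their flux families;
* `calibrate()` and the `estimate_*()` functions — the full derivation of
  the default coefficients from bulk physiological constraints;
* `simulate_generations()`, `fit_growth_rate()`, `cn_ratio()`,
  `quiescent_steady_state()` — deterministic lineage simulation with
  event-located division at volume doubling;
* `scan_parameter()`, `normalized_gradient()`, `rp_r_curve()` — parameter
  scans and unit-normalized sensitivity profiles of λ, C/N and steady
  volume;
* `run_population()` — a stochastic population simulator with a
  volume-dependent division hazard, noisy symmetric division, and optional
  two-protein synthesis regulation for proteome-distribution studies;
* `run_config()` / `run_analysis()` and a thin CLI
  (`inst/cli/cngrowth.R`) tying the modules together with
  provenance-stamped CSV/JSON output.

## Worked example

```r
library(cngrowth)

org <- organism_params("yeast")
traj <- simulate_generations(org$state, org$params, org$modes$rich,
                             n_generations = 8, gen_horizon = 20)
traj
#> <growth_trajectory> rich regime, 1615 points over 16.071 h, 8 division(s)

lam <- fit_growth_rate(traj)          # discards 3 transient generations
cn  <- cn_ratio(traj)
cat("lambda:", round(lam, 3), " doubling:", round(log(2)/lam, 3),
    " C/N:", round(cn$steady, 2), "\n")
#> lambda: 0.346  doubling: 2.001  C/N: 10.57
```

The cell doubles every 2 hours (λ ≈ 0.35/h) and settles at a C/N ratio of
about 10 — the published values for budding yeast. The quiescent regime
instead reaches a fixed point:

```r
ss <- quiescent_steady_state(org$state, org$params, org$modes$quiescent)
cat("volume:", round(ss$volume, 2), " C/N:", round(ss$cn, 2), "\n")
#> volume: 30.71  C/N: 3.03
```

The default coefficients themselves are derived, not asserted — the
calibration chain reproduces them from physiological constraints (2 h
cycle, 2000 ribosomes/min, 150000 ribosomal proteins imported/min, ...):

```r
calibrate("yeast")
#> <calibration_report> organism: yeast (derived)
#> conversion factor: 0.6106 x10^6/um^3
#> <kinetic_params>
#>     s1     s2     s3     n1     n2     n3     t1     t2     t3     t4     t5
#> 155.00 125.00  48.00 400.00 400.00  80.00 400.00   9.00   1.20   0.80   0.72
#>    d1C    d1N    d2C    d2N    d3C    d3N     r1     r2
#>   0.10   0.10   0.10   0.10   0.10   0.10   0.60   0.60
```

See `vignette("cell-growth-model")` for the model's assumptions, the
calibration arithmetic (including two documented inconsistencies in the
source tables and how the fixtures resolve them), and the stochastic
population machinery.

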