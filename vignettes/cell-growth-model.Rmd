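---
title: "A coarse-grained model of eukaryotic cell growth and nuclear size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of eukaryotic cell growth and nuclear size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngrowth)
```

## The model

Eukaryotic cells show a tight proportionality between cell volume and
nuclear volume, with a cell-type- and condition-dependent C/N ratio
(total cell volume over nuclear volume). `cngrowth` implements a
coarse-grained dynamical model that explains this proportionality from the
kinetics of the ribosome cycle and nucleocytoplasmic transport. Seven
molecular pools are tracked, in units of $10^6$ molecules: the free
cytoplasmic amino-acid pool $A_C$; non-ribosomal protein $P_C, P_N$; free
ribosomal protein $RP_C, RP_N$; and assembled mature ribosomes $R_C, R_N$,
split between cytoplasm ($C$) and nucleoplasm ($N$).

The processes are:

* **Translation** (cytoplasm): sequential assembly by mature ribosomes. The
  production rate of a protein of length $n$ is proportional to the
  amino-acid concentration and to the concentration of ribosomes at the last
  elongation step (a fraction $1/n$ of active ribosomes):
  $\dot P_C = s_1 A_C R_C / (n_1 V_C)$ and
  $\dot{RP}_C = s_2 A_C R_C / (n_2 V_C)$, consuming
  $(s_1+s_2) A_C R_C / V_C$ amino acids.
* **Ribosome assembly** (nucleus): $n_3$ ribosomal proteins form one
  ribosome at assembly sites whose abundance scales with nuclear content:
  $\dot R_N = (s_3/n_3) RP_N$, $\dot{RP}_N = -s_3 RP_N$. Subunit-level
  detail (40S/60S) is deliberately ignored: complete ribosomes are
  assembled in the nucleus and exported.
* **Transport**: amino-acid import contributes
  $\frac{V_C}{V_C+V_N}\,\bar t_1$ to $A_C$, where $\bar t_1 = t_1 P_C$ when
  external amino acids are rich (transporter abundance scales with the
  proteome) and a constant when they are poor. Carrier-mediated fluxes
  across the nuclear envelope scale with cargo concentration and with $P_C$
  (the carrier pool): $RP$ import $t_2 RP_C P_C/V_C$, ribosome export
  $t_3 R_N P_C/V_N$, and bidirectional non-ribosomal exchange with net
  import $(t_4 P_C/V_C - t_5 P_N/V_N)P_C$.
* **Degradation and disassembly**: bimolecular in growing cells (substrate
  meets machinery that scales with the compartment's protein pool), e.g.
  $-d_{1C} P_C^2/V_C$; disassembly returns $n_3$ ribosomal proteins per
  ribosome, and degraded protein is recycled into the amino-acid pool
  scaled by $V_C/(V_C+V_N)$.

Volumes close the system: from ion-and-water homeostasis, compartment
volume is proportional to the number of osmotically active macromolecules,
$V_C = (P_C+R_C+RP_C)/r_1$ and $V_N = (P_N+R_N+RP_N)/r_2$ with
$r_{1,2} \approx 0.6\times10^6/\mu m^3$. Free amino acids equilibrate with
the ionic system and do not enter the volume law, and the nuclear
amino-acid pool is not tracked (the nuclear share of import and recycling
is dropped). DNA's osmotic contribution is neglected.

Because every flux is first-order homogeneous in the state once volumes are
proportional to counts, balanced exponential growth is a solution: all
seven components grow at a common rate $\lambda$ and all ratios — including
C/N — become constant. This is the mechanism behind the observed
cell-nucleus size correlation.

## Growth regimes

`growth_mode()` selects among three regimes:

* **rich**: $\bar t_1 = t_1 P_C$ — exponential growth (yeast:
  $\lambda \approx 0.35\,h^{-1}$, 2 h doubling).
* **poor**: $\bar t_1$ constant (2850 for yeast, 15000 for the mammalian
  set) — asymptotically linear growth; the C/N ratio oscillates within each
  cycle because a linearly growing cell cannot relax to a balanced state.
* **quiescent**: constant uptake, reduced assembly ($s_3 = 5$ yeast / 0.3
  mammalian) and every bimolecular degradation term replaced by first-order
  decay at $d$ (0.8 yeast / 0.05 mammalian) — a constant-volume fixed
  point. The stoichiometric structure is kept: disassembly still yields
  $n_3$ ribosomal proteins and degraded protein is still recycled. The
  decay applies with the same rate in both compartments and with a negative
  sign for ribosomes; a positive ribosome-decay sign would contradict the
  synthesis-degradation balance that defines quiescence. These choices are
  deliberate interpretations where the source description is loose.

## Parameter calibration

Defaults are not fitted; they are derived (`calibrate()`) from bulk
physiology of budding yeast: a 2 h cycle, a 30 μm³ newborn (27 cytoplasm /
3 nucleus), 200 mM free amino acids, $27\times10^6$ cytoplasmic proteins of
which 45% are ribosomal, a 9:1 cytoplasm:nucleus split of free ribosomal
protein, 2000 ribosomes assembled per minute, 150000 ribosomal proteins
imported and 2000 ribosomes exported per minute, and degradation at 1/10 of
synthesis. Balances are struck at the *average* cell state, $\approx 1.3$
times the newborn (the time-average of an exponentially doubling cell);
the ribosome-production balance uses its own historical correction, dividing
the newborn $RP_N$ by 0.75. Both conventions are honored per derivation so
every printed coefficient is reproduced exactly
($s_3 = 48\,h^{-1}$, $t_1 = 400\,h^{-1}$, $t_2 = 9$, $t_3 = 1.2$,
$t_4 = 0.8\,\mu m^3/10^6 h$, $d = 0.1\,\mu m^3/10^6 h$).

Three arithmetic quirks of the source derivation are preserved and exposed
rather than silently repaired:

* The protein partition leaves $P_C = 27 - 80\cdot0.135 - 1.35 = 14.85$,
  which the reference tables print as 15 and use downstream. `calibrate()`
  therefore evaluates the kinetic balances at the tabulated counts
  (`reference_state`), while `build_initial_state()` returns the raw
  partition.
* The synthesis budget solves to $s_1+s_2 \approx 288$ raw; the
  conventional rounded budget 280 is split 11:9 (the proteome's own P:RP
  ratio) and rounded to the printed 155/125. The raw value is exposed in
  the calibration report.
* The non-ribosomal export coefficient: the derivation ("net import slightly
  positive") gives $t_5 = 0.9\,t_4 = 0.72$, while the summary table prints
  0.75. Only 0.72 reproduces the published steady C/N of 10 and
  $\lambda = 0.35$, so the yeast fixture defaults to 0.72; 0.75 is one
  override away. For the mammalian set the printed $t_5 = 0.05 = t_4/2$
  places the model far beyond the sharp growth transition at $t_4 = t_5$
  and the simulated cell collapses; applying the same
  "slightly-below-$t_4$" rule ($t_5 = 0.9\,t_4 = 0.09$) recovers the
  published 20 h cycle and C/N of 5.5, so 0.09 is the fixture default.

The mammalian parameter set is a literature-scaled set, not re-derived;
`calibrate("mammalian")` returns the fixture. Mammalian tabulated volumes
(1500/500 μm³) are inconsistent with $r = 0.6$ applied to the tabulated
counts; volumes are always derived from counts (1210/302.5 μm³ at the
newborn counts).

## Numerical choices

* **Integration**: `deSolve::lsodar`, relative tolerance $10^{-8}$,
  absolute $10^{-10}$. Division is located by root-finding on
  $V_{cell} - 2V_{birth}$, because division-timing accuracy propagates
  directly into C/N estimates; at division every component is halved
  exactly. Symmetric halving is a simplification (budding yeast divides
  asymmetrically); it does not affect $\lambda$ or the steady C/N.
* **Transients**: the first 3 generations are discarded for $\lambda$ and
  C/N estimates; deterministic runs use 8 generations (a 20 h per-generation
  horizon for yeast, 120 h for mammalian cells).
* **Quiescent steady state**: integrated in chunks until
  $\max_i |\dot x_i|/x_i < 10^{-6}\,h^{-1}$, horizon 200 h (yeast) or
  2000 h (mammalian); non-convergence is flagged, not hidden.
* **Growth-rate fit**: least-squares slope of log total volume vs time,
  with $\log 2$ added per completed division so the per-cycle log-increments
  concatenate into one line.
* **Sensitivity**: central finite differences at ±1% of each parameter
  normalized by its baseline ($\bar s = s/s^0$), assembled into a vector
  and scaled to unit Euclidean length. The 1% step balances truncation
  error against simulation noise. Degradation pairs are tied across
  compartments ($d_1, d_2, d_3$), and in the quiescent regime $s_3$,
  $\bar t_1$ and the single $d$ refer to the regime overrides. Scans default
  to logarithmic grids spanning 1/10x to 10x of the fixture value, 25
  points per axis; negative growth rates (shrinking cells) are reported,
  not clamped.
* **Scan responses**: steady C/N and RP/R are final-cycle means; a scan
  point that fails to divide falls back to fitting the final half of its
  trajectory and is flagged unconverged.

## The stochastic population simulator

`run_population()` doubles as the package's synthetic-data generator: it
produces single-cell ensembles with realistic size and proteome dispersion
from three stochastic ingredients layered on the deterministic equations:

1. **Initialization**: each cell is the newborn reference state scaled by
   an independent Uniform(1, 2) factor — "evenly distributed between one
   and two times the initial conditions". The factor is shared across a
   cell's components, preserving composition; the alternative
   (component-wise independent factors) would start cells far off the
   balanced-growth manifold.
2. **Division timing**: a division-volume distribution $\omega(V)$ over
   cytoplasmic volume; the default is Normal with mean $2 V_{C,birth}$ and
   CV 0.1, truncated to positive support, which reduces to deterministic
   doubling as the width shrinks. The source leaves $\omega$ unspecified;
   this choice reproduces division-at-doubling in the zero-noise limit.
   Each Euler step (dt = 0.02 h, hours assumed) a cell divides with the
   survival probability over the step's traversed volume,
   $1 - S(V_{after})/S(V_{before})$ with $S = 1 - \int_0^V \omega$. This
   integrates the hazard $k(V) = \omega(V)/S(V)$ exactly over the step, so
   the division-volume distribution converges to $\omega$ independent of
   dt. Sampled division volumes still sit slightly below the $\omega$ mean
   ($\approx -\sigma^2/\mu$): event sampling in a growing population
   over-weights fast-cycling small dividers. This is a property of growing
   populations, not a numerical artifact.
3. **Partition noise**: the newborn volume difference
   $(V_1-V_2)/V_{div} \sim N(0, 0.125)$; the split fraction is
   $f = 1/2 + \delta$ with $\delta \sim N(0, 0.125/2)$, resampled to stay
   in (0, 1) and applied identically to every constituent, so mass is
   conserved exactly at each division. The 0.125 is read as the standard
   deviation of the *difference between the two newborn volumes* (the
   stated definition), not of the split fraction itself; the doubled noise
   of the latter reading washes the regulated proteome correlations below
   into a linear cloud.

For proteome-distribution studies the non-ribosomal pool can be split into
two species P1, P2 with separate synthesis coefficients
(`regulation_spec()`): equal (77.5/77.5), unequal (65/90), enhancement
($s_{1,2} = 6 P_1$, counts in $10^6$) and suppression
($s_{1,2} = 145 - 5 P_1$, clamped at zero). Regulation acts on synthesis
only; transport and degradation treat P1+P2 as one pool, applied pro rata,
so one species recovers the base model exactly. Equal synthesis yields a
unit P2-vs-P1 slope (co-growth alone correlates proteins); enhancement
bends the joint distribution toward $P_2 \propto P_1^2$; suppression makes
it concave, $P_2 \propto P_1 - P_1^2$. Population runs cap at a configured
size by keeping a uniform random half and doubling a bookkeeping factor, so
extensive totals (used for the ensemble growth-rate check) remain
interpretable.

What the generator does *not* emulate: extrinsic and gene-expression noise
(all cells share one parameter set; stochasticity enters only through
initialization and division), cell-cycle phase structure, asymmetric
budding, age-dependent division hazards, and measurement error. Passing
tests on these ensembles therefore demonstrate the model's internal
consistency and the division machinery's statistics, not agreement with any
particular experimental single-cell dataset.

## Problem sizes

Deterministic checks use 8 generations (6 for scans) and the horizons
above. Population checks use 150-200 initial cells, a 2000-cell cap, and
10-26 simulated hours, which yields $>10^4$ division events for the
division-noise and division-volume statistics. These sizes hold every
reported statistic well inside its tolerance while keeping a full run of
the test suite around half a minute.

## Known limitations

* The model is coarse-grained by design: no individual genes or proteins,
  no mRNA dynamics, no 40S/60S subunits, no nucleolar phase separation, no
  mechanical coupling (pressure, cytoskeleton, lamins) — the volume law
  absorbs all of ion homeostasis into $r_{1,2}$.
* The poor-nutrient C/N ratio has no single steady value; the summary
  reports the final-cycle mean with its min/max band.
* The quiescent fixed point is found by forward integration, not
  root-finding on the governing equations; pathological parameter sets can
  exhaust the horizon and are flagged.
* Calibration reproduces the printed coefficient set, including its
  internal rounding conventions, rather than a statistically estimated
  parameter set with uncertainties.
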