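---
title: "Modelling combined oncolytic virotherapy and anti-CTLA-4 blockade"
author: "ovtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combined oncolytic virotherapy and anti-CTLA-4 blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovtsim)
```

## The model and its assumptions

`ovtsim` simulates the interaction of a growing melanoma with an engineered
oncolytic virus (OV) and an anti-CTLA-4 antibody in a mouse, at the
population level. Nine coupled ODEs track susceptible (`Tu`) and infected
(`Ti`) tumor cells, free virions (`V`), CD8⁺ (`X`) and CD4⁺ (`Y`) T cells,
the tumor-suppressive cytokine IFN-γ (`C`), CTLA-4 molecules (`W`),
anti-viral immune cells (`Z`) and natural killer cells (`N`). The main
structural assumptions:

* Tumor cells grow logistically with a shared carrying capacity `K_t`;
  infection converts susceptible to infected cells through a saturated
  contact term `β_t Tu V/(m_v + Tu)`.
* CD8⁺ T cells kill tumor cells directly (Michaelis–Menten in `X`); CD4⁺ T
  cells kill only indirectly, through the IFN-γ they drive
  (`δ_c T C/(m_t + T)`); NK cells kill tumor cells, clear free virions
  (`d_v N V`) and are themselves inactivated by tumor contact.
* Lysis of an infected cell releases `b_t` virions; infected-cell debris
  recruits anti-viral immunity (`p_v Ti`) which clears both infected cells
  and free virus.
* CTLA-4 molecules, expressed by activated T cells at rates `r_x` and `r_y`,
  inhibit CD4⁺ activation (`1/(1+νW)`) and cytokine production by all three
  producer populations (`1/(1+b·W)` factors). The antibody enters as a
  blockade fraction `u` scaling CTLA-4 expression by `(1 − u)`.
* Treatment is a constant-rate infusion: the OV dose rate `s` (PFU/day) and
  blockade fraction `u` apply on the half-open window
  `[start_day, start_day + duration)` and are zero outside. The reference
  protocol is 5 days from day 8 post-implantation, when the tumor has
  reached 4×10⁷ cells (40 mm³ at 10⁹ cells/cm³).

The model deliberately excludes subcellular signalling, PD-1/PD-L1, T-cell
exhaustion, spatial structure and antibody pharmacokinetics beyond the
`(1 − u)` factor.

### The CD8⁺ proliferation term

The antigen-driven CD8⁺ source is implemented as
`a_x (Tu+Ti)/(h_x+Tu+Ti)` — saturating in total tumor burden and *not*
proportional to the current CD8⁺ count. An alternative reading multiplies
this term by `X`; both are available via the `x_prolif` argument of
`ovt_rhs()`/`ovt_simulate()`. The antigen-only form is the default because
it reproduces the three validation endpoints (day-18 tumor sizes of
1.86×10⁹ / 1.14×10⁹ / 4.04×10⁸ cells for untreated, OV-only and combined
arms) to within 0.3%, while the `X`-proportional form misses them by roughly
16%. The units of `a_x` (cell⁻¹ day⁻¹) are likewise consistent with the
antigen-only reading.

### Treatment-window semantics

The day-30 regrowth of the combined arm (to ≈ 2.57×10⁹ cells) discriminates
between window conventions: if the blockade persisted beyond day 13, the
simulated day-30 tumor would be roughly half that size. The half-open
window with both `s` and `u` switched off at `start_day + duration` is
therefore used throughout, and the window edges are explicit integration
breakpoints so the dose discontinuity never straddles a solver step.

## Parameters

`ovt_param_table()` lists all 45 constants with baselines, units and
plausible ranges. The key tunables:

* `s_dose` (PFU/day) and `u_block` (unitless, 0–1): the treatment levers.
  The validated protocol uses 2×10⁶ and 0.76.
* `gamma_c` (day⁻¹, baseline 34): IFN-γ decay; the single most influential
  parameter under combined therapy — halving it to ≈ 11.3 eradicates the
  tumor by day 18, doubling it to 68 more than doubles the day-18 tumor.
* `delta_c` (cells day⁻¹ (pg/mL)⁻¹, baseline 0.2): cytokine tumor-killing
  rate; `delta_c = 0.67` eradicates, `0.02` roughly quadruples the day-18
  burden.
* `d_v` (cell⁻¹ day⁻¹, baseline 0.12): NK clearance of free virions; the
  dominant virus-related parameter — fast NK clearance halts OV spread and
  rescues the tumor.
* `a_v` (PFU⁻¹ day⁻¹, baseline 2×10⁻⁶): T-cell recruitment by virions; its
  strong negative PRCC reflects that the combination works mainly by
  activating anti-tumor immunity rather than by direct lysis.

## Numerical choices

* **Solver.** Variable-order BDF (`deSolve::ode(method = "bdf")`) with a
  compiled right-hand side; `rtol = atol = 1e-8` for reported single runs.
  The state spans ten orders of magnitude, so small negative solver
  undershoot is inevitable: components in `(−atol, 0)` are clamped to zero
  for rate evaluation, and query-time states clamp undershoot above
  `−10⁻⁵`. A pure-R right-hand side (`compiled = FALSE`) integrates
  bitwise-comparably and serves as a cross-check, as does an independent
  per-term oracle in the test suite.
* **Grids.** Output is stored on a 0.25-day grid plus every integer day and
  the window edges; `state_at()` is exact on grid points. Halving the grid
  or tightening `rtol` to 1e-10 moves day-18 endpoints by < 10⁻⁴ relative.
* **Near-threshold endpoints.** Close to the eradication threshold
  (e.g. `u ≈ 0.93` at `s = 2×10⁶`) the day-18 tumor size is exquisitely
  sensitive to integration accuracy: at MATLAB-default-like loose
  tolerances the endpoint differs by several percent from the converged
  value (BDF, LSODA and Radau agree to six digits at `rtol = 1e-10`).
  `ovtsim` reports converged values; published near-threshold figures
  carry their own solver error of this size, which is why the package's
  validation checks allow wider bands there while eradication (Tu < 1)
  itself is robust.
* **Eradication.** The tumor counts as eradicated when `Tu < 1` cell
  (strict); `eradication_search()` bisects on this predicate.
* **Stability conditions.** Strict inequalities, matching the analytic
  condition for local asymptotic stability of the tumor-free equilibrium.

## Global sensitivity analysis

`gsa_run()` emulates a virtual trial of `n` mice (default 500): a Latin
hypercube over all 45 parameters plus a dummy column on (0, 1), one
simulation per mouse from day 8 to day 18, PRCC of the day-18 susceptible
tumor size against each parameter. Design choices:

* **Bounds.** Published intervals where they exist (e.g. `delta_x` ∈
  [0.0096, 4.8]); otherwise baseline/10 to 2× baseline. `u` is fixed by the
  scenario, not sampled. Because several bounds are conventions rather than
  measurements, exact PRCC magnitudes are not meaningful outputs; signs and
  rankings are, and those are what the test suite asserts.
* **PRCC.** Rank-transform (average ranks on ties), residualize each
  parameter's ranks and the output ranks on all other parameters'
  ranks, correlate the residuals. The tests verify exact agreement
  (10⁻¹⁰) with partial correlation computed by correlation-matrix
  inversion. Rows whose simulation fails are dropped listwise and counted;
  more than 5% failures aborts.
* **Dummy floor.** A parameter with no model effect is sampled alongside
  the real ones; only |PRCC| above the dummy's counts as significant.
* **Cohort solver tolerance** is `1e-6` (vs `1e-8` for reported single
  runs): PRCC depends only on output ranks, which integration error at this
  level cannot perturb except at exact ties, and the looser tolerance keeps
  a 3 × 500-run analysis under a minute.
* **OV-restricted analysis.** The `ov_params_only` scenario samples the ten
  virus-associated parameters (`b_t, gamma_v, delta_v, d_v, a_v, beta_t,
  m_v, a_t, p_v, gamma_z`) with everything else at baseline — emulating
  mice with identical tumors and immunity treated with viruses of varying
  character. The membership of this set is a documented package choice.

What the virtual cohort does *not* emulate: inter-mouse variability in the
initial state or schedule adherence, measurement noise, or parameter
correlations — every parameter is sampled independently. Passing structural
checks on this cohort therefore says the *model's* sensitivity structure is
reproduced, not that biological mice would rank parameters identically.

## Problem sizes used by the test suite

Single-scenario checks integrate 10–22 model days; sensitivity checks run
the full 500-mouse cohorts for the three scenarios; property tests use 100
random state/parameter draws for the right-hand-side oracle and synthetic
(non-ODE) outputs for the dummy-floor repetitions, which keeps the dummy
property at 20 seeded repeats without re-simulating 10,000 mice.

## Known limitations

* Parameter baselines are a literature patchwork for the B16 murine system;
  transferring them to other tumor models requires re-calibration.
* The deterministic ODE cannot represent stochastic extinction: `Tu < 1` is
  a proxy for eradication, and sub-cell tumor sizes (e.g. 10⁻³ cells) are
  numerically meaningful but biologically fictive.
* Near-threshold protocol outcomes are extremely sensitive to `u`, `s` and
  integration accuracy; thresholds reported by `eradication_search()` are
  sharp for the model but should be read with ±1% humility for the biology.
* No pharmacokinetics: `s` and `u` are constant over the window, which
  idealizes the five daily injections of the underlying experiment.
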