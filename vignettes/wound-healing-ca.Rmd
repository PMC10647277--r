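---
title: "A lattice model of scratch-assay wound closure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of scratch-assay wound closure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scratchCA)
```

## The model

The scratch (wound-healing) assay seeds a monolayer, removes a strip of cells,
and tracks the normalized cell-free area $A(t)/A_0$ as the gap refills.
`scratchCA` represents the monolayer as a two-dimensional lattice of square
elements of side $\delta$ (one cell diameter, default 20 µm), with at most one
cell per site. The initial domain has three vertical zones: a central wound
band of $n_W = \mathrm{round}(b_0/\delta)$ empty columns, flanked by two
reservoirs each $\lceil n_W/2 \rceil$ columns wide whose sites are occupied
independently with probability $f = \min(1, \rho\,\delta^2)$, the occupancy
fraction corresponding to the seeding density $\rho$ (cells/µm²). Densities
above confluence are clamped to $f = 1$ with a warning. Rows are periodic (the
field of view is a cut-out of a much wider wound); the first and last columns
are reservoir edges: any vacancy there refills with probability $f$ each step,
so the far field holds its seeding density while supplying cells indefinitely.

Each cell is characterized by two times: the migration time $T_m$ (time to
travel one cell diameter; $T_m = \delta^2/D$ for motility coefficient $D$) and
the doubling time $T_d$. One sweep of the automaton advances physical time by

$$\Delta t = \left(\tfrac{1}{T_m} + \tfrac{1}{T_d}\right)^{-1},$$

so the per-step probabilities are exactly rate × time,
$P_m = \Delta t/T_m$ and $P_d = \Delta t/T_d$, with $P_m + P_d = 1$:
an unconstrained cell migrates at rate $1/T_m$ and divides at rate $1/T_d$.
Each sweep visits every occupied site once in a fresh random permutation
(asynchronous update with in-place mutation, which removes target-site
conflicts by construction). A visited cell draws $\lambda \sim U(0,1)$; if it
has no empty Moore (3 × 3) neighbor it is quiescent — contact inhibition — and
the draw is discarded; otherwise it migrates into a uniformly chosen empty
neighbor when $\lambda < P_m$, and otherwise stays put while a daughter
occupies a uniformly chosen empty neighbor. Diagonal moves cover
$\delta\sqrt2$ but count as one step, an inherent lattice approximation.

### Isotropy and the optional wound-directed bias

A directional bias toward the wound (mimicking a chemical stimulus from the
opposite edge) is implemented but **off by default**: cells on the left of the
wound center column can lose their backward sites as targets — by default the
two backward diagonals, reducing the 9-site block including self from 9 to 7 —
with the mirror image on the right and no bias on the center column itself. A
stronger variant (`bias_exclude = "all"`) removes all three backward sites.
The default is isotropic because the measured kinetics demand it: with
$T_m = 0.075$ h a biased front would advance at a large fraction of the
free-cell speed $\delta/T_m \approx 267$ µm/h and close a 371 µm wound in
under two hours, whereas measured HT-1080 fronts move at
$v = \alpha b_0/2 \approx 24$ µm/h — the speed of an unbiased
diffusion-plus-growth (Fisher-type) front. Isotropic closure is therefore a
*pulled front*: it emerges from random motility and division, not from drift.

### Measuring the wound

In vitro, the wound area is read off micrographs by variance-based edge
detection: the measured region is the macroscopic cell-free zone. The lattice
analogue used here is the number of empty sites **within the initial wound
band** that belong to a cell-free patch of at least two sites (at least one
empty Moore neighbor), times $\delta^2$. Two deliberate properties:

* *Pioneer cells do not truncate the wound.* Measures based on contiguous
  empty runs or connected components centered on the wound axis collapse as
  soon as sparse pioneers cross the centerline — long before the bulk front
  arrives — which makes $A(t)/A_0$ steeply convex and inflates the fitted
  closure rate roughly 2.4-fold relative to measured HT-1080 kinetics. An
  image-based detector does not resolve single cells as "monolayer", nor
  single vacancies as "wound".
* *Isolated single-site pores do not count.* A lone vacancy inside the
  repopulated sheet is ordinary monolayer texture below detection scale.
  Counting such pores delays nominal closure by several hours (they are only
  removed by a division landing in them, at rate $\approx 8 P_d$ per sweep)
  and would put the 100%-closure time for the HT-1080 benchmark near 13 h,
  far from the observed ~9 h; excluding them yields ~8 h.

The per-row-run and connected-component variants were implemented and
compared during development; the band measure above is the only one that
reproduces both the measured closure rate (within a few percent of
0.128 h⁻¹ for HT-1080 at $\rho = 2.9\times10^{-3}$) and the near-linear
decline of $A/A_0$ seen in experiments.

### Closure kinetics

`fit_closure_rate()` extracts:

* $\alpha$ (h⁻¹): minus the OLS slope of $A/A_0$ versus $t$ from $t = 0$
  until $A/A_0$ first reaches 0.1 (default), which excludes the flat closed
  tail; clamped at 0.
* $T_{1/2}$: first crossing of $A/A_0 = 0.5$, linearly interpolated between
  sweep samples (sampling can be coarse when $\Delta t$ is large).
* $T_{closure}$: first time the measured area is exactly zero; `NA` when the
  horizon is reached first.
* $v = \alpha b_0/2$: the two fronts share the areal closure rate; this
  definition is consistent with the physiological ranges of $v$, $\alpha$ and
  $b_0$ jointly.

## Sensitivity analysis

`run_gsa()` repeats, 10 times at full scale: draw 500 Latin hypercube samples
of $(T_m, T_d, \rho)$ from their physiological ranges
($T_m \in [0.005, 0.5]$ h, $T_d \in [12, 40]$ h,
$\rho \in [10^{-6}, 10^{-3}]$ cells/µm²; $\delta = 20$ µm and $b_0 = 575$ µm
fixed — they only set the lattice scale), simulate each, and fit

$$\mathrm{Output} = \beta_0 + \beta_\rho \rho + \beta_{T_m} T_m + \beta_{T_d} T_d$$

by OLS for each output ($\alpha$, $T_{1/2}$, $T_{closure}$). Inputs and
outputs are z-score standardized before the regression: raw-scale
coefficients of parameters with different units are not comparable, and the
subsequent ranking is only meaningful on standardized effect sizes. Replicate
distributions of $|\beta|$ are compared per output by one-way ANOVA with
Tukey's HSD at 95%; parameters are ranked 1–3 by mean $|\beta|$, with
non-significant Tukey pairs sharing the better rank, and an equally weighted
average of per-output ranks gives the overall ranking (the weights are a
documented knob).

The GSA horizon is 48 h — the upper end of standard scratch-assay durations
(published assays, including the benchmark cell lines here, span roughly
8–48 h). $T_{1/2}$ and $T_{closure}$ are *assay observables*: conditions that
have not closed within the assay are right-censored in reality, so
simulations are capped at the same horizon and non-closing runs are excluded
from the $T_{closure}$ regression, with the exclusion count reported.
This choice matters scientifically: with a multi-day horizon every sparse,
slow condition eventually closes and seeding density dominates the
closure-time regression — a regime no real assay observes — whereas at assay
duration the migration time dominates every output, density matters most for
the early observable $T_{1/2}$, and the doubling time matters most for full
closure. Replicate regressions with $p \ge 0.05$ are retained but flagged.

## The closure-rate scaling law

`phi_sweep()` draws $T_m$ log-uniformly (so the dimensionless ratio
$\Phi = T_m/T_d$ covers its span evenly on the log scale) and $T_d$, $\rho$
uniformly, simulates each condition (240 h cap: the sweep measures the
model's intrinsic rate, and $\alpha$ is a slope, well-defined for long runs),
and `fit_power_law()` fits

$$\alpha = a\,\Phi^{-b}$$

by OLS of $\log\alpha$ on $\log\Phi$ — the exact linearization under
multiplicative noise, which is what closure-rate fluctuations look like.
Non-closing and non-positive pairs are excluded with a logged count; standard
errors of $a$ propagate from the intercept by the delta method. At 300
simulations the fitted constants are $a \approx 1.2\times10^{-3}$ h⁻¹ and
$b \approx 0.59$–$0.66$ across master seeds.

`critical_phi_analysis()` quantifies when proliferation matters: for each
$\Phi$ on a grid it runs matched-seed pairs of simulations with division
enabled versus disabled ($P_d$ forced to 0 with the migration draw unchanged;
quiescence untouched) at fixed $T_d = 24$ h, full reservoir coverage and
$b_0 = 575$ µm, and reports
$\varepsilon(\Phi) = |\bar\alpha_{full} - \bar\alpha_{no\,division}| / \bar\alpha_{full}$
on the ensemble means (20 seeds per grid point by default), plus the smallest
grid $\Phi$ where $\varepsilon$ exceeds a configurable threshold (default
10%). $\varepsilon$ rises monotonically with $\Phi$, and above
$\Phi \approx 0.1$ the single fitted power law systematically under-predicts
the simulated rate (by roughly a factor of 3–4, i.e. predictions ≈ 0.25–0.3 ×
simulation), because closure there is proliferation-assisted and no longer on
the migration-scaling branch.

One quantitative caveat the knockout makes explicit: the number of divisions
per cell during closure scales like $T_{closure}/T_d \approx K\sqrt\Phi$ with
$K \approx 8$ for this geometry, so at $\Phi = 10^{-2}$ each cell divides
about once before the wound closes and removing division changes $\alpha$ by
far more than 10% ($\varepsilon(10^{-2}) \approx 0.6$ here; the 10% crossover
sits near $\Phi \approx 4\times10^{-4}$). A 10%-of-$\alpha$ knockout
criterion is therefore a much stricter notion of "proliferation negligible"
than locating the regime where the power-law scaling of $\alpha$ against
$\Phi$ holds, which is the sense in which a critical $\Phi$ of order
$10^{-2}$ is usually quoted.

## Numerical and design notes

* **Update order and RNG.** One seeded generator drives everything in a run:
  initial seeding, per-sweep permutation (Fisher–Yates), action draws, target
  draws, boundary refill. Identical parameters and seed give bit-identical
  trajectories; batch runs derive child seeds from a master seed. The
  compiled sweep consumes draws in a documented order that a plain-R
  transliteration reproduces exactly (this equivalence is under test).
* **Geometry rounding.** $n_W = \mathrm{round}(b_0/\delta)$, minimum 1;
  reservoir widths $\lceil n_W/2 \rceil$; the lattice defaults to square.
  Coordinates are 1-based `(row, col)` in R; the wound band is stored as an
  inclusive column range and the wound center column is fixed at
  initialization (it orients the optional bias).
* **Degenerate inputs.** Non-positive times, sizes or densities are rejected
  with the offending argument named; parameters outside physiological ranges
  warn (suppressible); $\rho$ above confluence clamps $f$ to 1 with a
  warning; an empty-band geometry errors.
* **Fit windows and ties.** The $\alpha$ window end is the first sample at or
  below the floor (default 0.1), with a minimum of 3 points; $T_{1/2}$ uses
  linear interpolation; ranks tie only when Tukey says the pair is
  indistinguishable at 95%.
* **Synthetic fixtures.** `make_synthetic_experiment()` emulates a measured
  $A/A_0$ series as $\max(0, 1 - \alpha t)$ plus truncated Gaussian noise
  clipped to $[0, 1.05]$. It reproduces the *shape and noise scale* of
  digitized assay curves, not imaging artifacts, edge-detection bias, drift,
  or cell-line-specific curvature — so fixture-based agreement shows the
  comparison plumbing and rate recovery are sound, not that the model matches
  any particular real dataset.
* **Problem sizes.** The shipped tests and the acceptance script use 20-seed
  ensembles for the calibration condition, a 300-simulation sweep, a 10 × 100
  GSA and a 7-point × 20-seed knockout grid; these reproduce the full-scale
  (2000-simulation, 10 × 500) results to well within their tolerances while
  keeping a complete run in minutes on one core.

## Known limitations

* The model is 2-D, single-layer, with no chemotaxis fields, ECM mechanics,
  contact guidance or cell spreading; cells are lattice squares of one size.
* The wound-area measure is tied to the initial band; wounds that drift or
  deform (not possible under these rules) would need the connected-region
  variant.
* At very low occupancy ($f \ll 0.1$) closure is reservoir- and
  division-limited and closure times become long and broad; such conditions
  are right-censored at the assay horizon in the GSA by design.
* The power law is phenomenological; no mechanistic claim is attached to the
  exponent, and above $\Phi \approx 0.1$ it is known to under-predict.

## A worked example

```{r example, eval = FALSE}
library(scratchCA)

p <- ca_params(Tm = 0.075, Td = 24, rho = 2.9e-3, b0 = 371, delta = 20,
               seed = 1, warn_range = FALSE)
traj <- simulate_wound(p)
fit_closure_rate(traj)

g <- run_gsa(n_samples = 100, n_replicates = 10, master_seed = 7)
g$ranks

sw <- phi_sweep(300, master_seed = 1)
fit_power_law(sw)
```
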