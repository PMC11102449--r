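---
title: "A hybrid lattice model of hypoxia- and adenosine-mediated tumor escape under DC immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid lattice model of hypoxia- and adenosine-mediated tumor escape under DC immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypadsim)
```

## The model

`hypadsim` simulates the interplay between a growing solid tumor, the
cellular immune response, and two immunosuppressive factors of the tumor
microenvironment — hypoxia and extracellular adenosine — under combinations
of three treatments: a hypoxia-inhibitor drug (a Px-478-like HIF inhibitor),
an adenosine-production inhibitor (a CD73-silencing siRNA nanoparticle), and
a dendritic-cell (DC) vaccine. It is a hybrid model: individual cells are
agents on a 2-D lattice, oxygen follows a discretized diffusion equation,
and the drug and adenosine pools follow ordinary differential equations.

### Lattice and agents

Cells occupy an `N x N` grid (`N = 210` by default, 10 µm site spacing, at
most one cell per site) with Moore (8-site) neighborhoods and no
wrap-around. Time advances in 2-minute steps. Six agent types exist: tumor
cells, inactive/active DCs, inactive T cells, regulatory T cells (Tregs) and
effector cells. Per step, each agent (in a freshly shuffled order, which
removes scan-order bias; the rule-application order within a step is
otherwise unspecified by the biology) applies its interaction rule and then
moves:

* **Tumor cells** divide with probability
  $\bar P_{tumor} = P_{tumor} + r_{Ht}/(U+c) + r_{At}\,Ad$
  (clamped to $[0,1]$), evaluated at the oxygen $U$ of the mother's site and
  the global adenosine level $Ad$. The daughter takes a uniformly random
  empty Moore neighbor; a fully enclosed cell cannot divide, so only the rim
  proliferates. Tumor cells neither move nor die naturally.
* **Inactive DCs** adjacent to tumor activate with probability
  $D_{act}$ per step; **active DCs** adjacent to a Treg revert with
  probability $D_{inact}$ (and are re-activatable later).
* **Inactive T cells** adjacent to an active DC activate with probability
  $C_{act}$; the activated cell becomes a Treg with probability
  $\bar P_{Treg} = P_{Treg} + r_{Hr}/(U+c) + r_{Ar}\,Ad$ (evaluated at the
  activating DC's site — tolerogenic conditioning of the DC), otherwise an
  effector. The total T lineage is conserved (no proliferation or death).
* **Effectors** with tumor neighbors pick one uniformly and kill it with
  probability $\bar\mu = \mu - r_{He}/(U+c) - r_{Ae}\,Ad$ (floored at 0
  under severe hypoxia/adenosine), at most one kill per step, surviving to
  kill again (serial killing).

Inactive (surveilling) immune cells perform a Levy walk: run lengths are
drawn from the discrete power law $F(z) = 1 - z^{-l}$ ($l = 1.15$) via
inverse transform ($z = \lceil (1-u)^{-1/l} \rceil$), with the direction
drawn uniformly among currently empty neighbors; blocked moves are skipped
but still consume the run; at the boundary the stored direction is mirrored
(a bounce). Activated cells move by Brownian motion (uniform over the 8
directions, moving only onto empty in-grid sites). Decrementing the run on
blocked moves (rather than pausing) avoids deadlocked pile-ups; the choice
is otherwise behaviorally neutral.

### Oxygen and hypoxia

Boundary sites are held at the vessel concentration `U_boundary = 0.8` mMol
(Dirichlet condition). Each step, the grid is partitioned into fixed,
non-overlapping 3×3 blocks; block `b` updates as

$$U_b \leftarrow \alpha A_b + (1-\alpha) U_b - \bar f\,\phi_b + k\,px,$$

where $A_b$ is the mean over the (truncated) 3×3 neighborhood *of blocks*,
$\phi_b$ is the fraction of the block's nine sites occupied by tumor,
$\bar f = 0.0023$ mMol is the per-site tumor consumption, and $k\,px$ is the
spatially uniform oxygen restoration by the hypoxia-inhibitor drug. The
updated value is redistributed to all nine sites, negatives are clamped and
the boundary re-imposed. Taking $A_b$ over the block neighborhood is the one
reading of the 3×3-block scheme that actually transports oxygen between
blocks under a fixed partition: with a block-local average the update would
decouple the blocks entirely and interior oxygen could never change, which
would contradict both the published spatial oxygen patterns and the scheme's
fixed point. The scheme is exactly idempotent on the uniform boundary value
and relaxes monotonically to it in the absence of tumor.

Hypoxia is the inverse of oxygen, $1/(U+c)$ with $c = 0.01$ guarding the
anoxic limit; it feeds the three modulated probabilities above and the
adenosine source below.

The diffusion coefficient $\alpha \in (0,1)$ has no published value; the
package defaults to $\alpha = 0.5$ (equal weight on local retention and
neighborhood mixing) and exposes it in the parameter set.

**Initial oxygen.** By default the field starts at the no-tumor steady
state — uniformly `U_boundary` — representing vascularized tissue that has
equilibrated before tumor implantation; hypoxia then *develops* as the tumor
consumes oxygen, reproducing the published pattern of an oxygen trough
around the growing mass. A literal anoxic start
(`initialize_state(oxygen_init = "zero")`) is retained for comparison: with
one diffusion sweep per step the front needs over a thousand steps to reach
the center, during which the maximal hypoxia term drives per-step division
probabilities near 0.25 and the tumor fills the grid within two simulated
days — a transient we judged unphysical (implanted tumors grow in oxygenated
tissue) and inconsistent with the moderate growth the model is meant to
reproduce.

### Adenosine and the vaccines

A single well-mixed adenosine pool obeys

$$\frac{dAd}{dt} = \beta + \frac{a}{U_{\mathrm{eff}}+c} - r\,Ad - \gamma\,S_t\,Ad,$$

with basal production $\beta$, hypoxia-driven production $a/(U+c)$,
first-order elimination $r$ and inhibition by the adhesion-filtered siRNA
level $S_t$. Because the pool is global while oxygen is spatial, a summary
$U_{\mathrm{eff}}$ is needed; the package uses the mean oxygen over tumor
sites and their Moore neighbors (the compartment where adenosine is
produced and acts), falling back to the grid mean when no tumor exists.
This choice is configurable in the sense that any state summary can be
computed from the recorded field; the tumor-neighborhood mean is the
documented default.

**Timescale.** The adenosine rates are read as *per day* and the balance is
integrated by forward Euler at `dt = dt_minutes/1440` (1/720 day per
lattice step). Read instead as per-2-minute-step rates, the pool would
equilibrate to its fixed point $Ad^* = (\beta + a/(U+c))/r \approx 188$
within the first simulated hour, whereas the modeled biology has adenosine
accumulating over the whole 18-day course with a late acceleration as
hypoxia deepens — and the resulting early division probabilities would
saturate the grid within days. The steady state itself is independent of the
step size, so all closed-form checks are unaffected. The module operation
`step_adenosine()` defaults to a unit step in the ODE's own time unit;
`adenosine_dt()` gives the engine's conversion.

The two drugs follow bolus-decay pharmacokinetics per lattice step:
$px \leftarrow (px + \text{dose})(1-\eta)$ on dose steps with
$\eta = 0.014$ (half-life ≈ 1.6 h; the hypoxia inhibitor is rapidly
cleared) and dose 40; the siRNA level $s$ likewise with
$\lambda = 0.002$ (half-life ≈ 12 h) and dose 4200. The nanoparticle
adheres and accumulates in the tumor area, modeled by a moving average of
the last `M = 800` steps (≈ 1.1 days), zero-padded before the history
fills; the filtered $S_t$, not the raw $s$, is what inhibits adenosine —
the filter exists precisely to model the drug that persists in the tumor
area, and it is only meaningful if $s$ itself decays on the same timescale,
which is why the PK rates stay per-step.

### Treatments and protocols

The eight experimental groups combine: Px-478 on days 6, 8, 10, 13, 15;
siRNA on days 6, 9, 12, 15; DC vaccine (70 pre-activated DCs placed
uniformly at random on empty sites) on day 7. `variant_protocol()` produces
the dose/timing variants (moving the DC day, scaling doses, every-k-day
schedules from day 6 through 17, daily alternation of the two inhibitors).
Day *d* maps to step `d * 720`; boluses are applied at the first step of
the day, before the humoral and field updates.

## Simulation conditions and defaults

All defaults follow the calibrated parameter table (reproduced in
`default_parameters()`; `?default_parameters` describes every field and its
units). The initial condition is one tumor cell at the grid center and 100
inactive DCs plus 750 inactive T cells at distinct uniformly random sites.
Runs are bit-reproducible from `(seed, params, protocol)`; replicate `i` of
an experiment uses `seeds[i]`, one RNG stream per replicate.

Recording defaults to every 60 steps (2 h). Replicate summaries report
daily means with 95% confidence intervals of the mean
(`1.96 sd/sqrt(n)`), the horizon-averaged tumor volume and the final-day
volume. Tumor volume converts occupied sites to mm³ via
`sites x 1e-4 mm² x 2200` = 0.22 mm³/site, the monolayer-to-3D expansion
calibration; the factor is exposed for recalibration. The "rim effector"
access metric counts effectors within Chebyshev distance 2 of any tumor
site; the radius is a documented choice mirroring the "effectors around the
tumor" readout.

```{r example, eval = FALSE}
p <- default_parameters()
run <- run_simulation(p, group_protocol("siRNA+Px-478+DC"), seed = 1)
tail(run$trajectory[, c("day", "volume_mm3", "n_effector", "adenosine")])
```

## Sensitivity and identifiability analyses

`global_sensitivity()` perturbs named parameters jointly and uniformly
within ±50% of their defaults by Latin-hypercube sampling, runs the
untreated model per sample (averaging a few stochastic replicates), and
ranks parameters by the partial rank correlation coefficient (PRCC) between
parameter and horizon-averaged tumor volume. PRCC is the standard statistic
for monotone input–output relations under LHS; the response function is
pluggable, so other statistics or outputs can be substituted.

`identifiability()` computes central finite-difference sensitivity
trajectories (default ±10%, common random numbers for the paired runs) of
seven outputs — tumor volume, adenosine, hypoxia, ambient cytotoxicity, and
effector/Treg/active-DC counts — and flags a parameter pair as
non-identifiable only when their sensitivity trajectories are collinear
(|Pearson r| ≥ 0.9) in *every* output. The effector-averaged cytotoxicity
is also recorded but is undefined while no effectors exist, so the
screening uses the always-defined ambient value
$\bar\mu(U_{\mathrm{eff}}, Ad)$.

Both analyses are expensive at full scale, so the packaged checks and the
acceptance script run them at a reduced scale chosen as the package's own
study condition: a 90-site grid with immune counts scaled by area
(preserving densities), a 12-day horizon for sensitivity (long enough for
the daily-timescale adenosine pool to differentiate its parameters while
the tumor still fits the smaller grid) and a 10-day horizon for
identifiability, 100 hypercube samples across 10 parameters with 2
replicates each. The vignette-level claim these runs
support is qualitative — which parameter group dominates, and whether any
pair is collinear — not the full-scale index values.

## What the synthetic checks do and do not show

The package ships no empirical data. Test fixtures are built in code, and
`synthetic_reference_curve()` provides a smooth logistic volume curve as a
stand-in reference for goodness-of-fit (`rsq()`) demonstrations; it is
labelled synthetic and carries no information about real tumors. Passing
tests therefore establish internal correctness (exact oracles, conservation
laws, distributional properties, cross-checks between the R module
operations and the compiled engine) and qualitative agreement with the
modeled biology — they do not validate the model against mouse data, which
would require the original caliper measurements.

## Numerical choices, degenerate inputs, limitations

* Probabilities from the modulated-rate formulas are clamped to $[0,1]$;
  oxygen is clamped at 0. Both clamps are documented floors, not fitted.
* The Levy inverse CDF returns the smallest $z$ with $F(z) \ge u$; a
  one-ulp correction guards the integer boundaries. $z = 1$ occurs only on
  the measure-zero draw $u = 0$.
* Fisher–Yates shuffles and index draws consume one uniform each, so runs
  are exactly reproducible and the compiled engine can be mirrored draw-
  for-draw in R (the tumor-only oracle test does exactly that).
* DC boluses exceeding the number of empty sites fill all empties and warn.
  Degenerate analysis inputs (constant reference series, zero sampling
  range, inert parameters) raise errors or warnings rather than silent
  results.
* Known limitations: no angiogenesis or vascular remodeling (boundary
  vessels only), no tumor natural death or metastasis, no immune
  proliferation/death or healthy-cell compartment, no spatial drug
  diffusion, no feedback of adenosine onto hypoxia, 2-D monolayer geometry.
  Because a rim-adjacent effector kills roughly two orders of magnitude
  faster than a rim cell divides under the per-step reading of the immune
  contact rates, simulations operate in an immunosurveillance-with-rare-
  escape regime: most replicates — including untreated ones (roughly 9 in
  10) — end in eradication, and ensemble means are driven by the minority
  of escape trajectories in which the tumor outruns effector recruitment
  and locks in the hypoxia/adenosine feedback. Replicate summaries should
  therefore be read as means over a bimodal eradication/escape mixture,
  and across-protocol comparisons carry wide confidence intervals.
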