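---
title: "A mechanohydraulic model of cotton fiber elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanohydraulic model of cotton fiber elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersim)
```

## The system and the model

A cotton fiber is a single epidermal cell of the seed coat that elongates
enormously while barely changing diameter. `fibersim` treats it as a
cylinder of volume $V$ growing in length only, connected to the seed both
apoplastically (water crossing the plasma membrane, conductivity $L_r$,
mostly set by aquaporins) and symplastically (water and solutes advected
through plasmodesmata, total permeability $\mu$). The seed proper is
assumed to be a large, equilibrated reservoir: its osmotic pressure
$\pi_\mathrm{seed}$ and turgor $P_\mathrm{seed}$ are constant, and the
apoplast is in equilibrium with it.

Two state variables evolve: the volume $V$ and the fiber osmotic pressure
$\pi_\mathrm{fiber}$. Water fluxes are driven by water-potential and turgor
differences,

$$\frac{dV}{dt} = F_m + F_p,\qquad
  F_m = L_r V (\Delta\pi - \Delta P),\qquad
  F_p = -\mu \Delta P,$$

with $\Delta\pi = \pi_\mathrm{fiber} - \pi_\mathrm{seed}$,
$\Delta P = P_\mathrm{fiber} - P_\mathrm{seed}$. The membrane flux scales
with $V$ because the lateral area of an elongating cylinder is proportional
to its volume ($A_m = 2V/r$ at fixed radius; the per-area permeability and
the radius are absorbed into $L_r$). Wall expansion is irreversible and
viscoplastic (Lockhart):

$$\mathrm{rgr} \equiv \frac{1}{V}\frac{dV}{dt} = \phi (P_\mathrm{fiber} - Y)_+ ,$$

elastic deformation being neglected (longitudinal elastic strains are a few
percent, the plastic strain is a thousand-fold). Solutes enter at a
normalized rate $\alpha$ (expressed directly in Pa/s of osmotic pressure,
which avoids ever instantiating particle numbers or $RT$), are diluted by
growth, and are advected through plasmodesmata with the concentration of
whichever side the water comes from:

$$\frac{d\pi_\mathrm{fiber}}{dt} = \alpha
  - \frac{\pi_\mathrm{fiber}}{V}\frac{dV}{dt}
  + \frac{\mu \pi_\mathrm{seed}}{V}(-\Delta P)_+
  - \frac{\mu \pi_\mathrm{fiber}}{V}(\Delta P)_+ .$$

Fiber turgor is not integrated: equating the water balance with the growth
law yields a piecewise-linear equation for $\Delta P$ whose closed form has
a *no-growth* branch (below the yield surface the balance is purely
hydraulic) and a *growth* branch (the wall yields and $\phi/L_r$ enters the
denominator). The two branches agree exactly on the switching surface, so
$\Delta P$ is continuous in the state; `delta_P()` implements this closed
form, and the test suite checks it against an independent bracketing
root-solve of the flux balance at $10^{-10}$ relative tolerance.

Assumptions worth keeping in mind: no solute diffusion through
plasmodesmata (advection only — justified while open plasmodesmata keep the
osmotic difference small), no spatial gradients along the fiber, no radius
dynamics, and a seed reservoir unaffected by what the fiber takes from it.

## Parameters, ranges, reference point

The seven parameters carry literature-derived biological ranges, packaged
in `inst/extdata/parameter_ranges.csv` (SI units):

```{r}
default_parameter_table()[, c("parameter", "x_min", "x_max", "x_ref", "unit")]
```

The reference point is the geometric mean of each range — the natural
midpoint for ranges spanning up to eight decades (plasmodesmal
permeability). Relative deviations `x_min/x_ref - 1` and `x_max/x_ref - 1`
quantify the asymmetry that motivates the maximal-change analysis below.
Initial conditions for the standard runs are $V(0) = 1.88\times10^{-4}$
mm$^3$ and $\pi_\mathrm{fiber}(0) = \pi_\mathrm{seed}$ (iso-osmotic start,
which puts initial fiber turgor slightly above seed turgor, as measured);
the standard horizon is 500 h, comparable with the natural duration of
fiber growth. Only the first few hours depend on the initial conditions.

## Numerical choices

* **Units.** Strict SI internally (m³, Pa, s); hours/MPa/mm³ only at the
  I/O boundary, with exact conversion constants. Configuration files must
  tag every quantity with a unit, and bare numbers are rejected — a silent
  factor of $10^9$ between mm³ and m³ is the characteristic failure mode of
  this kind of model.
* **State vector.** The integrator works on $(\log V, \pi_\mathrm{fiber})$.
  Volume grows by factors up to $10^{80}$ in 3,000 h closure sweeps;
  log-volume keeps relative error uniform and guarantees positivity.
  Results are invariant (to tolerance) under integrating $V$ directly.
* **Non-smoothness.** The positive parts in the growth law and the solute
  advection are implemented exactly, not smoothed: smoothing would shift
  the growth threshold, to which the sensitivity table is sensitive.
  Integration uses `deSolve`'s `lsoda` (adaptive, stiffness-switching —
  solute exchange is fast compared to growth when plasmodesmata are wide
  open), and is restarted at every schedule breakpoint instead of letting
  the stepper discover discontinuities.
* **Window membership.** Closure windows and pulses are closed intervals
  $[t_0, t_0 + t_\mathrm{dist}]$. During integration, membership is frozen
  per segment (decided at the segment midpoint), which only affects a
  measure-zero set of evaluation times but makes runs bit-reproducible.
* **Tolerances.** Defaults `rel_tol = 1e-10`, `abs_tol = (1e-12, 1e-4)`;
  halving them moves the 500 h final volume by less than $10^{-6}$
  relative. Sensitivity runs use `1e-11`/`(1e-13, 1e-5)` because the
  smallest tabulated sensitivities are of order $10^{-5}$ and their signs
  must be resolved by 1% central differences.
* **Output grid.** 2,001 uniform samples by default — resolves 50 h
  closure windows within 500–3,000 h horizons. Analyses in this vignette
  and in the test suite use 201–1,001 samples where that resolution
  suffices.
* **Extremum detection.** The first 5% of the horizon is discarded (initial
  transient), and a point counts as an extremum only if it exceeds both
  neighbors by more than $10^{-9}$ relative — a guard against flagging
  solver ripple on plateaus. Degenerate flat trajectories are labeled
  `monotonic_increasing` by convention; this only matters for frozen
  systems.
* **Steady state.** `detect_steady_state()` reports the earliest time from
  which $|dX/dt| \cdot t_\mathrm{max}/X$ stays below the tolerance (default
  1%) for both pressures: "would change by less than 1% of itself over the
  whole horizon at the current rate".

## The reference run

```{r}
params <- reference_parameters()
traj <- simulate_fiber(params, output_grid = 501)
traj
detect_steady_state(traj) / 3600  # hours
classify_pressures(traj)
```

Both pressures rise monotonically from the iso-osmotic start and level off
shortly after 400 h; the relative growth rate becomes constant as soon as
they do. Early on, the fiber is small, so plasmodesmal solute leakage
(scaling as $\mu/V$) caps the osmotic pressure; as the fiber grows the
leak becomes negligible and the pressures climb to the balance point where
the solute source just compensates dilution.

## One-factor-at-a-time sensitivity

`oat_sensitivity_table()` perturbs each parameter to
$x_\mathrm{ref}(1 \pm h)$ (default $h = 1\%$, well inside the $\pm 10\%$
exploration window) and central-differences the three observables: the log
volume gain $\log(V(t_\mathrm{max})/V(0))$ (natural log) and the final
pressures. The normalization $S = (x_\mathrm{ref}/X)\,\partial X/\partial x$
makes entries dimensionless and comparable:

```{r}
tab <- oat_sensitivity_table(output_grid = 101)
round(matrix(tab$S, 3, 7,
             dimnames = list(unique(tab$observable),
                             unique(tab$parameter))), 4)
```

The derivative is step-size converged: halving $h$ changes the large
entries by about $10^{-5}$ relative (`check_convergence = TRUE` records
this per parameter). Signs are readable directly from the physics: the
solute source and extensibility promote growth; plasmodesmal permeability
and seed osmotic pressure drain the fiber's advantage; membrane
conductivity barely matters because the membrane is not limiting at the
reference point.

## Maximal change over the biological ranges

Local sensitivities implicitly assume equal relative variation. The ranges
are wildly unequal, so `maximal_change()` sweeps each parameter over its
full range on a log-spaced grid (endpoints included — for monotone
responses the extremes are then exact) and reports the observable's total
swing normalized by its reference value. The grid is converged by
$n_\mathrm{grid} = 33$; the ranking is already stable at 7–9 points.
Three parameters — plasmodesmal permeability, the solute source, and wall
extensibility — dominate all three observables, which is what motivates
the dynamic-parameter scenarios.

## Why constant parameters cannot produce pressure peaks

Measured fiber turgor and osmotic pressure *peak* mid-development. With
constant parameters the model cannot do that for biologically plausible
values: a peak requires the solute source to fall below a combination of
the other parameters (`peak_condition()`), and over the entire biological
range that threshold is smaller than any admissible $\alpha$ by more than
ten orders of magnitude. Note that the inequality as printed in the source
literature is dimensionally heterogeneous; `peak_condition()` evaluates it
verbatim and flags this, and the package treats the numerical classifier as
the source of truth: on hundreds of log-uniform draws from the ranges
(`generate_fixture()`), every constant-parameter trajectory is monotonic in
both pressures. The supplementary analytic enumeration of behavior types is
not re-derived here.

## Dynamic parameters

`run_scenario()` wires time-dependent overlays into the simulator:

* `phi_decay` — extensibility falls linearly from its reference value at
  0 h to zero at 500 h (wall stiffening: cellulose content rises and
  microfibrils reorient as the fiber matures). Growth arrests as
  $\phi \to 0$ and the final pressures end up *below* the reference run's.
* `mu_closure` — plasmodesmata close on 200–250 h (as reported
  mid-development in vivo). The trapped solutes push both pressures through
  a pronounced peak, followed by a transient drop below trend after
  reopening.
* `alpha_pulse` — the solute source steps to the top of its biological
  range on the same window. A peak appears but is several-fold smaller
  than the closure peak (peak heights are measured against the
  constant-parameter run at the same times), suggesting solute dynamics
  alone is a weaker lever than plasmodesmata gating. The pulse onset and
  duration mirror the closure window by default and are configurable; a
  rectangular step stands in for the original ramp, whose exact shape is
  not public.
* `combined` — both `phi_decay` and `mu_closure`; the peak survives and
  growth still arrests.

```{r}
sc <- run_scenario("mu_closure", output_grid = 501)
sc
```

`closure_sweep()` maps the final volume at 3,000 h over the closure start
$t_0$ and duration $t_\mathrm{dist}$, normalized by the anchor cell
($t_0 = 200$ h, $t_\mathrm{dist} = 50$ h, always re-simulated with the
identical configuration so the anchor entry is exactly 1). Earlier and
longer closure both favor longer fibers, monotonically across the grid;
the default grids are $0, 50, \ldots, 500$ h on both axes (the anchor and
monotonicity properties are grid-independent). Windows extending past the
horizon are clipped and flagged.

```{r, eval = FALSE}
m <- closure_sweep()          # 11 x 11 grid, 3,000 h horizon
```

## What the fixtures do and do not show

Property tests draw parameters log-uniformly and independently from the
biological ranges — matching the geometric-mean reference point, but
ignoring any correlations between parameters in real fibers (none are
quantified in the literature). The draws exercise the solver across regimes
from membrane-limited to wall-limited growth, including strongly stiff
corners (wide-open plasmodesmata in a small cell). Passing them shows the
implementation is faithful to the stated model over the stated ranges; it
does not validate the model against fiber growth data beyond the
qualitative behaviors discussed above, and the extreme final volumes
reached in long runs (the model has no intrinsic size limit unless
extensibility decays) are a reminder that constant-parameter extrapolation
is mechanistic, not predictive.

## Known limitations

Single cell, fixed radius, no tip geometry; no mechanistic model of
plasmodesmata gating (the closure window is imposed, not emergent); solute
handling is a single lumped pool with advective exchange only; the seed is
an infinite reservoir. These match the scope of the underlying model;
extensions would change the equations, not just parameters.
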