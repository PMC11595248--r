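---
title: "Two-phase logistic kinetics of induced hepatic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase logistic kinetics of induced hepatic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionkinetics)
```

## The model

In situ-induced hepatic lesions in a large-animal model grow rapidly for
about three weeks after inoculation and then, in many animals, regress
spontaneously. `lesionkinetics` models the cell count $N(t)$ of one lesion
with the logistic differential equation

$$\frac{dN}{dt} = \kappa\,N\left(1 - \frac{N}{\theta}\right),$$

where $\kappa$ (1/day) is the growth-rate constant and $\theta$ (cells) the
carrying capacity. CT measures volume, not cells; the two are linked by the
linear conversion $N = \alpha V$ with $\alpha = 146{,}997 \pm 15{,}738$
cells/mm^3, the cell density of normal swine liver parenchyma (1 µL is
treated as identical to 1 mm^3). The closed-form solution in volume space is

$$V(t) = \frac{\theta}{\alpha\,(1 + c\,e^{-\kappa t})},$$

with a dimensionless shape coefficient $c$ fixing the starting point
$V(0) = \theta/(\alpha(1+c))$. The curve is positive and singularity-free on
$t \ge 0$ whenever $c > -1$ and $\theta > 0$; `logistic_params()` enforces
exactly these invariants. `integrate_ode()` provides an independent check:
classical RK4 integration (via deSolve) of the ODE agrees with the closed
form to a relative tolerance of $10^{-6}$ across the parameter ranges the
package works in, and the test suite asserts this over 200 random parameter
sets.

Kinetics are two-phase: growth ($\kappa > 0$) is assumed from inoculation to
a breakpoint at day 21, regression ($\kappa < 0$) from day 21 onward. The
breakpoint day belongs to both phases, so both fits use it. The model is
defined only for existing lesions: baseline (day 0) scans carry volume 0 and
are excluded from every fit.

The packaged reference curves (`reference_params()`) are

| phase      | $c$        | $\kappa$ (1/day) | $\theta$ (cells)  |
|------------|-----------:|-----------------:|------------------:|
| growth     | 5.823      | 0.146            | $8.740\times10^8$ |
| regression | 5.909e-4   | $-0.360$         | $1.470\times10^9$ |

Evaluated at the breakpoint the two curves give 4676.5 and 4685.2 mm^3 — a
gap of 8.65 mm^3, under 0.2% of either value — so the independently fitted
phases are, for practical purposes, continuous at day 21.

## Fitting protocol

`fit_phase()` estimates $(c, \kappa, \theta)$ by unconstrained nonlinear
least squares in volume space (mm^3). Cell-space residuals are available and
change the objective only by the constant $\alpha^2$; the estimates are
identical. The default start is $c = -10$, $\kappa = \pm 0.1$ 1/day (sign
set by the phase), $\theta = 1.46997\times10^9$ cells
($146{,}997\ \text{cells}/\mu L \times 10^4\ \mu L$), with a total budget of
10,000 iterations. Convergence tolerances (relative step, objective and
gradient) are $10^{-10}$ — deliberately tighter than needed, so that
recovery accuracy is limited by identifiability rather than stopping rules.
The Levenberg–Marquardt backend caps one call at 1024 iterations; the budget
is honoured by restarting from the last iterate until convergence or
exhaustion, and the reported iteration count is the total.

Two numerical design choices deserve explanation.

**Robust starts.** The default start $c = -10$ lies outside the valid
parameter region ($c \le -1$), and from it a plain Levenberg–Marquardt
descent reliably slides into a degenerate ridge: for large negative $c$ and
negative $\theta$ the model degenerates to a two-parameter exponential
$(\theta/\alpha c)e^{\kappa t}$, which fits three growth points tolerably
but not exactly, and the optimiser converges there with a non-zero residual.
Trust-region solvers escape this ridge; plain LM does not. `fit_phase()`
therefore always adds one data-driven candidate start whenever three or more
distinct timepoints are available: for fixed $\kappa$ the reciprocal volume
is linear in $e^{-\kappa t}$, $1/V = a + b\,e^{-\kappa t}$ with
$a = \alpha/\theta$ and $b = \alpha c/\theta$, so $\kappa$ is profiled over
a grid (step 0.01 on $[-1.5, 1.5]$, then refined by golden-section search)
with $(a, b)$ solved by linear least squares, and the minimiser is
back-transformed to $(c, \kappa, \theta)$. All candidate starts — the
configured one, the profiled one, and any random restarts requested via
`multistart` — are polished by LM and the lowest-rss solution wins, with
ties broken by start order for determinism. On noiseless data from the
reference growth curve this recovers the reference parameters to machine
precision from the default start.

**Under-determined fits.** The regression phase of the reference design
observes only days 21 and 28: two timepoints for three parameters. The
least-squares backend cannot even pose a 3-parameter problem on 2 residuals,
and no data could resolve one. `fit_phase()` flags such fits
(`identifiable = FALSE`, with a warning), holds $\theta$ at its
initialisation, and fits $(c, \kappa)$ only — for which the two-point
problem has a closed-form solution that is supplied as a second candidate
start. This behaviour reproduces the reference protocol's own signature: the
reported regression $\theta = 1.470\times10^9$ is the initialisation
$1.46997\times10^9$ to four significant figures, i.e. $\theta$ never moved.

**Aggregation.** By default observations enter the objective as per-day mean
volumes across lesions (`aggregate = "timepoint_mean"`), fitting one
population curve; `"pooled"` treats every lesion-scan as a residual and
`"per_lesion"` fits each lesion separately. The population default reflects
that a single overall curve is the headline result, with individual curves
as overlays. The choice matters for noisy data: a single lesion observed at
exactly three timepoints is interpolated exactly by the three-parameter
model, so measurement noise propagates undamped (and heavy-tailed) into the
estimates, whereas per-day means across ~28 takes are stable.
`recovery_experiment()` quantifies this: per-parameter bias and RMSE over
seeded replicates at any noise level.

**Sign handling.** $\kappa$ is not box-constrained; the phase-appropriate
sign comes from the initialisation, and a fitted sign contradicting the
phase label raises an advisory warning rather than an error.

## Summary rates and extrapolation

Fitted phases are summarised as linearised rates in mm^3/day
(`linear_rate()`), with two conventions:

* growth uses `from_zero`, $V(21)/21$ — the lesion is absent at inoculation,
  so the accumulated volume divided by elapsed time is the natural mean
  rate. With the reference growth curve this gives 222.69 mm^3/day.
* regression uses `difference_quotient`,
  $|V(21) - V(28)|/7 = 574.70$ mm^3/day with the reference regression curve.

The conventions differ because the alternatives do not reconcile with the
headline values these curves are known by: $(V(21)-V(0))/21 \approx 181$
mm^3/day for growth, for instance. A fundamental-theorem check in the test
suite confirms the difference quotient equals the mean instantaneous rate
$\alpha^{-1}\,dN/dt$ over the interval to $10^{-6}$.

`extrapolate_growth()` continues the growth curve 7 days past the breakpoint
alongside the regression curve; the disparity at day 28 — 5416.7 vs 662.3,
about 4754 mm^3 — is the quantitative picture of spontaneous regression.
`take_rate()` reports the fraction of inoculation sites ever detected.

## The synthetic cohort

No per-lesion measurements are publicly deposited for this model system, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, and every downstream stage is tested against it. The
defaults encode the study design itself: 9 animals, 4 sites each, sacrifice
groups of 3 at days 14/21/28, each scanned weekly from day 0 to sacrifice;
28 of 36 sites take. Where the design fixes no value, the defaults are
stated assumptions chosen once:

| parameter | default | rationale |
|---|---|---|
| `take_rate` | 28/36 | takes allocated *exactly* by seeded shuffling, not i.i.d. coin flips, so the realised ~78% is reproducible for any seed |
| `animal_kappa_cv` | 0.25 | growth rates vary widely between animals but are consistent within one; a mean-1 lognormal multiplier on $\kappa$ per animal, shared by both phases |
| `noise_cv` | 0.10 | multiplicative lognormal measurement noise; segmentation error scales with lesion size, and ~10% is a realistic repeatability figure for manual CT segmentation of soft-tissue lesions |
| `detection_limit` | 50 mm^3 | no threshold is documented for "fully regressed"; 50 mm^3 (~4.6 mm diameter) is a plausible conspicuity floor for a hypoattenuating liver lesion on portal-venous CT |
| `full_regression_prob` | 0 | complete regressions below the detection limit already emerge from the dynamics; a forced-zero option exists for stress-testing |

Each take follows the growth curve to the breakpoint and then a regression
curve made *continuous* with it: the regression shape coefficient is
rescaled per lesion so both phases agree at day 21, mirroring the
near-coincidence of the independently fitted reference curves. Observed
volumes are the true volumes times lognormal noise; values under the
detection limit (and all day-0 rows) are emitted as `detected = FALSE` with
volume 0.

What the generator does **not** emulate: CT grayscale content (contrast
phases, attenuation, partial-volume effects), anatomy-aware lesion placement,
registration error between timepoints, reader variability structure beyond
a single multiplicative noise term, and any immune mechanism behind
regression — the regression phase is descriptive kinetics, not mechanism.
Passing tests therefore demonstrate correctness of the pipeline on data
matching the model's assumptions, not robustness to the full messiness of
real CT studies.

`rasterize_lesions()` closes the imaging loop for testing: each detectable
lesion becomes a digital ball of exactly `round(V / voxel volume)` voxels
(the k voxel centres nearest the slot centre), so its voxelised volume is
within half a voxel of the truth, placed without overlap; maps are written
and read as NIfTI.

## Volumetry

`measure_label()` reports voxel count, volume and surface area per label.
Volume is exactly `voxel_count × sx·sy·sz` — exact to machine precision for
any rasterised box. Surface area uses the exposed-face estimator: the summed
area of voxel faces whose 6-neighbour carries a different label, array
boundaries counting as exposed. This estimator is deterministic and easy to
verify (600 mm^2 for a unit-spacing 10-voxel cube) but overestimates smooth
surfaces by up to ~1.5× relative to mesh-based estimates; since no
downstream model quantity consumes surface area, the bias is documented
rather than corrected. `island_filter()` keeps the largest 26-connected
component of a label (6-connectivity available), relabelling smaller islands
to background; ties go to the component containing the smallest linear
(column-major) voxel index. Components are found by breadth-first search on
the voxel lattice. Label maps are read from NIfTI with spacing taken from
the header (overridable); only spacing is used — world-coordinate
orientation is read but ignored, a documented limitation. NRRD input is not
supported.

## Numerical choices and problem sizes

Degenerate inputs are errors with named causes: empty phase selections,
fewer than two distinct timepoints, absent labels (listing the available
ones), all-background maps, unsorted time grids, impossible scan schedules.
Non-finite residuals during optimisation (from overflowing trial parameters)
are clamped to a large finite value so the optimiser can retreat.

The test suite runs entirely on generated data at deliberately modest sizes:
200 random parameter sets for the closed-form/RK4 equivalence (RK4 step 0.1
days there; the default is 0.01), 100-replicate recovery experiments,
100 replicate cohorts for the population-level bias check, label volumes up
to $96^3$, and digital spheres up to radius 40 voxels. These sizes keep the
whole suite under half a minute while leaving each property's verdict
unambiguous.

## Known limitations

* The two-phase structure is imposed, not inferred: the breakpoint is a
  parameter (default day 21), not an estimated changepoint.
* No per-animal mixed-effects modelling; the population fit averages over
  animals, and `animal_kappa_cv` exists only in the generator.
* No uncertainty propagation of $\alpha$ beyond carrying its stated SD.
* Surface areas are voxelised estimates; do not compare them against
  mesh-based values without accounting for the systematic difference.
* The regression-phase reference design (two timepoints) cannot identify
  $\theta$; every quantity derived from the regression $\theta$ inherits its
  dependence on the initialisation.
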