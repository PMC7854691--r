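---
title: "Modelling championship 10,000 m pacing as an optimal control problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling championship 10,000 m pacing as an optimal control problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 5)
library(trackpace)
```

## The model

`trackpace` treats a 10,000 m track race as a minimum-time optimal control
problem for a point-mass runner. Three states evolve with distance $s$ from
the start: the instantaneous speed $v$, the propulsive force per unit mass
$f$, and the remaining anaerobic energy per unit mass $e$ (the maximal
accumulated oxygen deficit). In the time domain,

$$
\dot v = f - v/\tau, \qquad
\dot f = u, \qquad
\dot e = \sigma(e) - f\,v,
$$

with the control $u \in [-u_-, u_+]$. The friction coefficient $\tau$
lumps all joint and track dissipation: $f_{\max}\tau$ is the runner's
absolute speed ceiling, and the steady-state energetic cost per metre at
speed $v$ is $v/\tau$, so a *smaller* $\tau$ models a runner with a
*higher* cost of running (worse running economy). The aerobic power
$\sigma$ is a function of the remaining anaerobic store, which acts as a
proxy for race phase; $u_\pm$ are motor-control limits on how fast effort
can be built up or shed.

Half of a 400 m lap is bend running. On a bend of radius $R$, part of the
force budget is consumed by the centripetal acceleration, which caps the
propulsive force:

$$ f^2 + \frac{v^4}{R^2} \le f_{\max}^2 . $$

The standard track is modelled as alternating 116 m half-circle bends
($R = 36.5$ m) and 84 m straights, starting on a bend; a 10,000 m race
crosses 50 of each, 5,800 m of bends in total. The printed 116/84 split is
measured on the 400 m line while the curvature refers to the kerb-offset
measurement line; the two are slightly inconsistent
($\pi \cdot 36.5 \approx 114.7$), and we deliberately keep both printed
values rather than reconcile them. All runners are placed on the
measurement line, ignoring the stagger and racing-line width, so the race
distance is exactly 10,000 m.

### The aerobic power curve

Only the plateau level of the aerobic supply is well anchored by
physiology (around 85% of a VO2max of 85 mL O2/kg/min for a world-class
championship 10,000 m, i.e. about 25.2 W/kg using 20.9 J per mL O2). The
shape of the curve is a modelling choice; we use a continuous three-piece
linear function of the remaining store:

* a **ramp** over the top $1 - \varphi_{\mathrm{ramp}}$ fraction of the
  store, rising from $\sigma_{\mathrm{rest}}$ at the gun to
  $\sigma_{\max}$ — oxygen-uptake kinetics at the start;
* a **plateau** at $\sigma_{\max}$ through the bulk of the race;
* a **final drop** below $\varphi_{\mathrm{final}}\,e^0$, falling to
  $\sigma_{\mathrm{final}}$ at exhaustion.

Defaults: $\sigma_{\mathrm{rest}} = 0.3\,\sigma_{\max}$,
$\sigma_{\mathrm{final}} = 0.8\,\sigma_{\max}$,
$\varphi_{\mathrm{ramp}} = 0.9$, $\varphi_{\mathrm{final}} = 0.2$. All
five numbers are exposed in the configuration. Because the drop makes
$\sigma$ increase with $e$ near exhaustion, holding a little energy back
has value, so exact exhaustion is not guaranteed in principle; in
practice the default optimum ends with the store effectively empty (well
under 2% of $e^0$).

The model permits partial re-synthesis of the anaerobic store when
$\sigma(e) > f v$. A hard cap $e \le e^0$ is inconsistent with the
collocation equations whenever the cap is active (the defect at the bound
cannot vanish), so re-synthesis instead *tapers* linearly to zero over the
top 2% of the store (`resynthesis = "taper"`); `"clip"` disables recovery
entirely. The taper width is a numerical smoothing choice, not a
physiological statement: it only matters for the few metres after the gun
during which aerobic supply exceeds demand.

### Default parameters

The packaged `default_winner.json` anchor set —
$e^0 = 1500$ J/kg, $f_{\max} = 8$ N/kg, $\tau = 1.55$ s,
$u_\pm = 0.25$ N/kg/s — produces a 26–27 minute optimal 10,000 m with a
~6.3 m/s cruise and a clear endspurt. These are plausibility anchors for
a generic world-class runner, not fitted values for any specific athlete;
tests against them assert ranges and directions, never exact race times.

## Tactical speed corridors

Championship races are tactical: free minimum-time pacing would be almost
even, whereas real races surge. We confine the optimisation to a *speed
corridor* — piecewise-constant lower/upper bounds per 100 m segment —
around either an observed (smoothed) speed profile
(`build_corridor()`) or a synthetic tactic template
(`tactic_corridor()`). Bounds are wide (±0.3 m/s) where the athlete
free-runs and tight (±0.1 m/s) where a strategic speed is imposed: the
start surge (0–200 m) and the mid-race surge (4,000–6,000 m) by default.
The smoothing centreline is a centred moving average over 4 segments
(edges truncated); the original's exact smoothing is unstated, so the
moving average is our choice.

Tactic templates anchor their relative profile at a cruise pace estimated
from the energy balance $D v/\tau = e^0 + \sigma_{\max} D / v$, which
matches the cruise speed of unconstrained solves to about 0.1%; a 0.995
margin keeps shaped profiles (which cost more than even pacing at the
same mean) feasible. Template multipliers are harmonically normalised so
the nominal race time is preserved. The corridor's lower bound tapers up
from `v_floor` over the first 100 m so the standing start is feasible.

## Numerical method

The problem is transcribed in the distance domain on a fixed grid over
$[0, D]$ (trapezoidal collocation), with states $(v, f, e)$ and control
$u$; elapsed time is eliminated and recovered afterwards by the exact
quadrature of $1/v$ for a piecewise-linear speed profile, so the reported
final time equals the integral of $1/v$ to machine precision. Curvature
is evaluated at interval midpoints to avoid constraint jumps exactly on
segment boundaries. A small smoothing term
$\varepsilon \int u^2/v\,\mathrm ds$ ($\varepsilon = 10^{-4}$) suppresses
bang-bang chattering and contributes well under 0.01 s to the default
race.

Choices that proved necessary, found by experiment during development:

* **Start-ramp grid.** The standing start ($v_{\mathrm{init}} = 1$ m/s,
  a floor of 0.5 m/s; the $1/v$ integrand is singular at rest) is
  resolved by a geometric ramp of spacings from 0.25 m; an unresolved
  start distorts the first-interval time by several seconds.
* **Coarse-to-fine continuation.** The start arc admits distinct local
  optima; fine grids started cold can land ~1% slower than the true
  optimum. We first solve on a ~200-node grid, re-integrate the coarse
  control onto the target grid with a fixed-step RK4 scheme, and polish.
  This makes solutions grid-consistent (0.2% between 150 and 600 nodes on
  a 1,500 m course) and is fully deterministic.
* **Augmented Lagrangian with safeguarded updates.** Collocation defects
  (in state-difference units, normalised by the mean spacing so penalty
  rows stay equally conditioned on the graded grid) and the bend
  constraint are handled by an augmented-Lagrangian outer loop around
  box-constrained L-BFGS (multiplier updates only when the violation
  halves; penalty weight capped at $10^7$). The energy state is scaled
  for the inner solver. Initialisation seeds the store-*exhausting*
  basin — a linear decay of $e$ and a terminal force ramp — because an
  energy-conserving initial path can trap the solver in a slow local
  optimum that never unlocks the aerobic plateau.
* **Convergence acceptance.** The target residual is `nlp_tol`
  ($10^{-7}$); residuals that stagnate below $10^{-4}$ (orders of
  magnitude below the discretisation error) are accepted, and a
  violation that refuses to fall for many iterations terminates the
  solve as infeasible rather than silently returning a partial result.

`verify_trajectory()` is the independent oracle: it re-integrates the
dynamics forward with fixed-step RK4 driving the solved force profile and
reports speed/energy deviations at 100 m marks plus the energy-balance
residual. Converged full-race solves reproduce speed to a few times
$10^{-3}$ m/s and energy to well under 1% of $e^0$.

## Calibration

`calibrate()` identifies $(e^0, f_{\max}, \tau, u_+, u_-, \sigma_{\max},
\sigma_{\mathrm{final}})$ from an observed 100 m split series by bounded
derivative-free minimisation of the RMSE between simulated and observed
mean segment speeds (`fit_error()`); the $\sigma$ shape fractions are
frozen to curb non-identifiability. Two design points matter:

* **Every evaluation is a cold solve.** Chaining warm starts between
  evaluations makes the objective depend on evaluation order, which
  silently corrupts a simplex search; cold continuation solves keep it a
  deterministic function of the parameters.
* **A diagonal pre-scan precedes the local search.** When every
  parameter is too generous the simulation saturates the corridor's
  upper bound and the objective is locally *flat* — a pure local search
  cannot start. Probing overall strength along $\theta_0 \cdot s$,
  $s \in [0.8, 1.2]$, finds the responsive region first (the same idea
  as fitting over "a wide range of parameters"), after which a simplex
  over the energetic triple $(e^0, \tau, \sigma_{\max})$ and then over
  all seven parameters refines the fit.

On zero-noise synthetic data with the generating corridor supplied, a
budget of 200 solves recovers $e^0$ and $\tau$ to well under 1% and the
final time to hundredths of a second from a 10% mis-scaled start. With
the corridor instead rebuilt from the observed splits, the moving-average
smoothing introduces a small bias floor (~0.05 m/s RMSE); directions and
identifiability are unchanged.

## Scenario experiments

`perturb_params()` scales one field and re-validates; `compare_scenarios()`
solves base and variant under the same corridor and summarises the finish
gap, per-split differences, an endspurt measure (mean speed over the last
400 m minus race mean) and the per-lap bend/straight gap. If the variant
cannot follow the baseline corridor, wide segments are relaxed by +50%
(tight strategic windows are kept) and the report is flagged — the
weaker-runner policy is our guess, flagged in output, since the original
experiments do not state theirs.

Two qualitative findings the package reproduces as property tests:

* **Anaerobic capacity gates the endspurt.** Reducing $e^0$ by 5% slows
  the optimum, with the largest per-split deficits in the final 400 m
  and a reduced endspurt; the effect is monotone in the reduction.
* **Bend running.** Curvature couples into the model *only* through the
  force cap, so at the default anchors (cap binding above ~11 m/s) the
  cruise is curvature-blind. Fitted championship profiles that oscillate
  on every bend imply a thin force margin; the packaged
  `bend_limited.json` set ($f_{\max} = 4.25$ N/kg, $\tau = 1.55$ s,
  $\sigma_{\max} = 26.5$ W/kg) has cruise demand just above the bend cap
  and reproduces the pattern: every cruise lap runs the straights faster
  than the bends (gap ≈ 0.18 m/s), and a 10% worse economy shrinks that
  bend/straight amplitude (measured as the RMS per-lap gap) because the
  force headroom $f_{\max}\tau - v$ for re-acceleration on the straights
  shrinks.

## Synthetic data

`generate_race()` closes the loop for testing: a tactic template builds a
corridor, the optimal race for known true parameters is solved, 100 m
splits are computed, and independent zero-mean Gaussian timing noise
(default sd 0.05 s per split, the plausible resolution of video-derived
timing) is added to the times, re-drawing any non-positive split. The
truth record keeps the parameters, tactic, corridor, seed, noise-free
splits and trajectory.

What the generator emulates: championship-style pacing (fast start,
variable cruise, a 4,000–6,000 m surge, endspurt from ~7,000 m), split
observables, and timing noise. What it does not: lane stagger and racing
line, wind, drafting and runner interaction, leg-level biomechanics, and
any correlation structure in real timing errors. Passing recovery tests
therefore demonstrates internal consistency of the estimation machinery,
not that real athletes' physiology is identified this precisely.

## Problem sizes and tolerances used by the test-suite experiments

Unit tests run short courses (400–2,000 m) at 100–300 nodes. The
acceptance experiments use the full 10,000 m race at the default 1,000
nodes (10 m spacing) for simulation/verification and 500 nodes for the
calibration study (budget 200 solves) and scenario comparisons — sizes at
which a full calibration completes in minutes on a single core while
grid-refinement error stays well below every asserted tolerance.

## Known limitations

* The optimum is a local one: the transcription is nonconvex, and the
  continuation strategy selects the racing-relevant basin rather than
  certifying global optimality.
* Identifiability of $u_\pm$ and $\sigma_{\mathrm{final}}$ from 100 m
  splits is weak; they stay near their initial values unless the data
  contain sharp transients.
* The bend effect at cruise pace exists only in the thin-force-margin
  regime; with a generous force ceiling the model predicts flat cruising
  across bends.
* Wind, altitude, temperature and inter-runner interaction are out of
  scope.

## A worked example

```{r example, eval = FALSE}
p <- default_winner_params()
trk <- track_geometry()
corridor <- tactic_corridor("championship_surge", p, trk)
traj <- solve_race(p, trk, corridor = corridor)
attr(traj, "final_time")
autoplot(traj)

splits <- compute_splits(traj)
autoplot(splits)

rep95 <- compare_scenarios(p, perturb_params(p, "e0", 0.95), trk,
                           corridor = corridor)
glance(rep95)
autoplot(rep95)
```
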