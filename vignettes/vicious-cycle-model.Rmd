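---
title: "A vicious-cycle kinetic model of amyloid-beta accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vicious-cycle kinetic model of amyloid-beta accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidcycle)
```

## The model

Soluble Abeta42 in the brain of the Tg2576 mouse rises from a baseline
of roughly 34 pg/mg at adulthood (1 month) to a plateau above
2000 pg/mg by 27 months, with a long latency, a steep mid-life rise and
a late saturation.  That time course is summarised by a logistic curve

$$A_\mathrm{logistic}(t) = 34 + \frac{2240}{1 + (t/18)^{-5.9}},$$

sampled at integer months $t = 1, \dots, 27$; these 27 values are the
target "data" every fit in this package works against
(`make_target_series()`).

A purely linear scheme $dA/dt = k_1 - k_2 A$ cannot reproduce this
shape: its closed-form solution grows fastest at $t = 1$ and
decelerates forever after, so it is never sigmoidal
(`linear_solution()`, `is_sigmoidal()`).  The package therefore models
the accumulation as a mutual positive feedback — a vicious cycle —
between Abeta ($A$, pg/mg) and an abstract disease factor ($X$,
dimensionless; it may stand for tauopathy, oxidative stress,
inflammation or any combination):

$$\dot A = V_1 \frac{X^n}{K_1^n + X^n} - k_2 A, \qquad
  \dot X = V_1' \frac{A^n}{K_1'^n + A^n} - k_2' X .$$

Each variable stimulates the other's production through a saturating
Hill term and decays with first-order kinetics.  The Hill coefficient
is fixed at $n = 2$, the smallest integer for which the fitted model is
sigmoidal; it is nonetheless carried as a parameter (`hill_n`) for
sensitivity work.  An optional zeroth-order production term (`basal`,
default 0) supports variants with a linear Abeta source.

### Parameters and their defaults

| field | meaning | unit | default |
|---|---|---|---|
| `V1` | feedback ceiling of Abeta production | pg mg^-1 mo^-1 | 1.36e6 |
| `K1` | half-saturation of Abeta production in X | — | 10.7 |
| `k2` | Abeta removal rate | mo^-1 | 450 |
| `V1p` | feedback ceiling of X production | mo^-1 | 0.998 |
| `K1p` | half-saturation of X production in A | pg/mg | 134.2 |
| `k2p` | X removal rate | mo^-1 | 0.00168 |
| `A_init`, `X_init` | state at 1 month | pg/mg, — | 34, 1 |

`k2 = 450` mo^-1 comes from the ~1.1 h turnover of soluble amyloid in
mice and is never fitted; `A_init` is the measured baseline and
`X_init = 1` an arbitrary but harmless normalisation of the abstract
variable.  The remaining five values are the fitted mouse
parameterisation and ship both as the in-code defaults of
`kinetic_params()` and as `inst/extdata/mouse_params.yaml`.

### Stiffness and integration

Abeta relaxes on the $1/k_2 \approx 0.002$-month timescale while $X$
relaxes on $1/k_2' \approx 600$ months — five orders of magnitude
apart.  `simulate_trajectory()` therefore integrates with LSODA
(automatic stiff/non-stiff switching) at relative tolerance $10^{-8}$
and absolute tolerances $10^{-10}$ (A) and $10^{-12}$ (X); halving the
tolerance moves $A(27)$ by well under 0.1%.  A consequence of the
separation is that Abeta sits in quasi-steady state with the
instantaneous $X$: along the fitted trajectory
$|A - (V_1/k_2)\,X^2/(K_1^2 + X^2)|/A$ stays below 2% from the second
month on (a tested invariant; the initial month is excluded because the
state $(34, 1)$ starts slightly off the quasi-steady manifold and A
snaps onto it within hours).

Interventions starting mid-life are parameter switches:
`simulate_piecewise()` integrates segment by segment, carrying $(A, X)$
continuously across each instantaneous, permanent parameter change.
Integration always starts at $t = 1$ month (adulthood), not 0.

## Fitting

`fit_vicious_cycle()` minimises the summed absolute log-ratio

$$\mathrm{LogErr} = \sum_{i=1}^{27}
  \left| \log_{10} \frac{A_\mathrm{pred}(i)}{A_\mathrm{target}(i)} \right|$$

over the free parameters $(V_1, K_1, V_1', K_1', k_2')$, holding $k_2$,
$A(1)$ and $X(1)$ fixed.  The base of the logarithm is hard-coded to 10
and regression-tested: refitting the default target reaches a summed
error of about 0.53 with parameters that round to the shipped defaults,
which is only consistent with the base-10 convention (the natural-log
value of the same fit is larger by a factor of $\ln 10$).  Evaluating
the objective at the shipped, 3-significant-figure defaults gives
0.658 — the objective is extremely sensitive at that precision (moving
$K_1$ from 10.7 to 10.75 changes it from 0.66 to 0.54), so the shipped
defaults should be read as the centre of a narrow valley rather than
its exact bottom.

Free parameters span several orders of magnitude, so optimisation runs
in log-parameter space: multi-start Nelder-Mead (Brent in 1-D), first
start at the reference values, further starts log-uniform within a
decade of them (clipped to the bounds, which default to $10^{\pm 3}$
times the reference).  The best start is polished by restarting the
simplex until it stagnates.  Everything is deterministic given `seed`.
The objective uses a relaxed solver tolerance ($10^{-6}$) for speed;
the reported `log_err` is re-evaluated at full tolerance.

### Identifiability

The data constrain only the observable $A$; the scale of the latent
$X$ is pinned solely by the convention $X(1) = 1$, whose influence
fades as $X$ grows a hundredfold.  The objective therefore has a
sloppy direction: noiseless synthetic targets are recovered to about
1% in $V_1, K_1, V_1', K_1'$ (medians over ten seeded replicates), but
$k_2'$ is only recovered to order of magnitude in single fits —
parameter sets differing in $k_2'$ by a factor of five can match the
27-point series to a summed log error below 0.01.  The recovery test
reports per-parameter medians rather than hiding this.
`profile_objective()` exposes one-dimensional slices of the objective
for the same purpose.

## Interventions

The dose of a permanent intervention on parameter $P$ with reference
value $P_0$ is $D = |1 - P/P_0|$: production ceilings ($V_1$, $V_1'$)
are scaled by $1 - D$ (capped at $D = 1$, total shutdown), removal
rates ($k_2$, $k_2'$) by $1 + D$ ($D > 1$ allowed).  The
half-saturation constants are not intervention targets.  Success means
$A(27) \le 100$ pg/mg — under 1/20 of the untreated endpoint; the
threshold is a configurable default, not a constant.

`min_effective_dose()` bisects the dose to a $10^{-3}$ tolerance,
relying on the monotone non-increase of $A(27)$ in dose, which is
itself a tested invariant over dose grids for all four targets and
several start ages.  On the default parameterisation the minimum doses
at a 1-month start are about 0.39 ($V_1$), 0.64 ($V_1'$) and 0.65
($k_2$), while $k_2'$ cannot reach the threshold even at dose 1
(infeasibility is returned as a result, not an error; its search cap
defaults to 10).  Starting at 15 months, the $V_1$ dose must exceed
0.9 — early intervention matters.

For combinations, `equal_dose_combination()` bisects one scalar dose
applied to both parameters, and `dose_surface()` +
`threshold_contour()` compute the full two-dose response surface (41
by 41 grid by default over $[0, 1]$ per production axis, $[0, 1.5]$
for $k_2$), extract the $A(27) = 100$ iso-effect contour by per-ray
bisection refined to 0.5 pg/mg, and report the contour point closest
to the origin in raw Euclidean distance — the "optimal combination".
The axes are deliberately unscaled; an analysis that weights removal
doses differently can rescale the grids.  `synergy_report()` labels a
combination *synergistic* when both optimal combined doses fall below
half the corresponding monotherapy doses, *hardly useful* when the
optimal point sits on an axis, and *favorable* otherwise.  The
equal-dose combination of $k_2$ with $V_1$ needs only ~0.24 per arm —
substantially less than either monotherapy — whereas combining the
two production ceilings yields ~0.28 per arm.

## Drift, not jump

`find_fixed_points()` reduces the steady-state problem to one
dimension by substituting the A-nullcline into the X-nullcline, scans
2000 log-spaced points of $X$ in $[10^{-6}, 10\,V_1'/k_2']$ for sign
changes (wide enough to capture tight root pairs near saddle-node
events), polishes each root by bisection, and classifies it from the
analytic Jacobian; non-hyperbolic eigenvalues are flagged rather than
forced into a class.  With the default parameterisation the system has
three fixed points: a stable origin (eigenvalues $-k_2$, $-k_2'$), an
interior saddle at $A^* \approx 3$ pg/mg, and a high stable state at
$A^* \approx 3000$ pg/mg.  The system is formally bistable, but the
saddle sits far below the 34 pg/mg starting level: the mouse is born
inside the high-state basin and never crosses a separatrix.  Disease
progression is a lifelong drift, not a bistable jump — the feedback
fitted to the data is so strong that it overwhelms the linear terms
that a jump would require.  `bifurcation_scan()` confirms the
geometry: scanning $V_1$ downward collapses the saddle and high state
in a saddle-node event, leaving only the origin.

Two practical notes.  First, deciding where a state ends up
(`basin_check()`) requires integrating far beyond the 27-month
lifespan, because $X$ relaxes over ~600 months; the implementation
doubles its integration window until the trajectory lands on a fixed
point (cap 20 000 months).  Second, a *successful* intervention need
not change the basin: halving $V_1$ keeps $A(27)$ under 100 pg/mg yet
the treated state still drifts — beyond the lifespan — toward the
(lowered) high state.  Only near-total feedback shutdown (dose ~0.9)
moves the initial state into the low basin.  The success criterion is
about the lifespan, not the asymptotics.

## What the synthetic data do and do not emulate

The generator produces (a) the exact logistic target at integer
months, (b) perturbed logistic curves (any constants, optional
multiplicative log-normal noise under a fixed private seed — the noise
model matches the log-ratio objective and preserves positivity), and
(c) forward-simulated trajectories from known kinetic parameters for
recovery experiments.  It does not emulate biological replicates,
measurement error structure of ELISA assays, censoring, or
animal-to-animal variability — the study's target is itself a smooth
fit, not raw data.  Passing recovery tests therefore demonstrates that
the machinery inverts its own model class, not that the model is
identified by real mouse measurements.

## Problem sizes and numerical choices in the tests

The shipped tests run the 27-point grid throughout; dose searches use
bisection to $10^{-3}$; surface tests use 7–9 point grids per axis
(the default 41 is for analyses); the recovery experiment uses ten
replicates with truths drawn log-uniformly within a factor of two of
the reference and four optimisation starts each.  Ties in
`is_sigmoidal()` resolve to the first maximal interval (`which.max`),
so a flat-growth series counts as non-sigmoidal.  Dose grids are
strictly ascending; solver failures inside a surface sweep are
recorded as missing cells rather than aborting the sweep.

## Known limitations

* The model is phenomenological at the organism level: one abstract
  $X$, no species resolution (monomer/oligomer/fibril), no spatial
  compartments, no pharmacokinetics of the interventions (switches are
  instantaneous and permanent).
* Only soluble Abeta42 in the Tg2576 mouse is modelled; nothing here
  is a human disease model.
* $k_2'$ is weakly identified from the Abeta series alone; any
  conclusion that leans on its exact value should be checked against a
  profile slice.
* Optimal combinations use unscaled Euclidean distance in dose space;
  with removal doses above 1 on one axis this choice is consequential
  and deliberately simple.
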