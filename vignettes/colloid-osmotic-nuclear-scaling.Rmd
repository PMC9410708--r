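---
title: "Colloid osmotic control of nuclear size: models and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colloid osmotic control of nuclear size: models and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoscale)
```

## The model

The cell and its nucleus are treated as two nested spherical osmometers.
Each compartment contains a fixed amount of osmotically active
macromolecules — species too large to pass the nuclear pore's passive
diffusion limit — plus a non-osmotic (dry) volume `b` that is not
available as free water. Water equilibrates so that across each membrane
the colloid osmotic pressure difference balances the Laplace pressure
`2 sigma / R` of that membrane:

$$(C^{Cy} - C^{out})\,R_{gas}T = \frac{2\sigma^C}{R^C},\qquad
  (C^{N} - C^{Cy})\,R_{gas}T = \frac{2\sigma^N}{R^N},$$

with $C^{N} = N^N/(V^N - b^N)$ and $C^{Cy} = N^{Cy}/(V^C - V^N - b^{Cy})$.
Small permeant molecules (ions, osmolytes that cross the envelope) drop
out of the nuclear balance; they matter only for the cell-surface balance,
which we absorb into the external concentration and an *effective* surface
tension $\sigma^C$. The steady state is unique, which is what makes a
bracketing solver globally convergent (see *Numerics*).

Two consequences organize everything else in the package:

* **Buffering.** If $\sigma^N \approx 0$ and the normalized non-osmotic
  volumes match ($\nu_b^N = \nu_b^C$), the N/C volume ratio equals the
  nuclear share of macromolecule amounts, $N^N / (N^N + N^{Cy})$,
  independent of the medium. Osmotic shocks then change both volumes
  proportionally.
* **Sensitivity.** Crowding mismatch ($\nu_b^N \neq \nu_b^C$) or
  appreciable nuclear-envelope tension make the ratio shock-sensitive;
  `nc_sensitivity()` scores the excursion (max − min over a sweep,
  relative to the isotonic value) and `phase_diagram()` maps it over the
  mismatch–tension plane, where the buffered valley sits at matched
  crowding and low tension.

### Units

Concentrations are in mOsm (≡ mol/m³), volumes in µm³, tensions in N/m,
temperature in K (default 303.15 K, i.e. 30 °C). Osmolyte amounts are
carried as concentration × volume (mOsm µm³); 1 mOsm µm³ is
6.022 × 10⁵ particles (`particles_from_amount()`), and a number density
converts to osmolarity via `osmolarity_from_density()` (30 × 10⁷
particles/µm³ ≈ 498 mOsm). These choices make the osmotic arithmetic
exact in the common zero-tension case and keep the Laplace term in SI.

The growth rate $\gamma_C$ is a first-order rate constant and is carried
in min⁻¹ throughout: $\ln 2 / 0.006\,\mathrm{min^{-1}} \approx 115$ min
reproduces the observed doubling time.

### Numerics

`solve_steady_state()` uses nested root bracketing. For a trial cell
volume the nuclear balance residual goes from $+\infty$ (as
$V^N \to b^N$) to $-\infty$ (as the cytoplasmic free volume collapses),
so the inner root is bracketed; the outer cell-surface residual behaves
the same way in $V^C$ on $(b^C,\, 10\,(N^{cell}/C^{out} + b^C))$. A
collapsed inner bracket is treated as a large positive outer residual,
which steers the outer search back into the feasible region. Relative
volume tolerance is 1e-10 by default; the returned `residual_norm` (mOsm)
makes convergence auditable. The test suite checks the solver against an
independent nested grid-search oracle and against the zero-tension closed
form `V − b = N/C_out` per compartment.

Spherical geometry is assumed for both compartments; involuted or
non-spherical shrunken nuclei are out of scope. $\sigma^C$ is a single
effective scalar — wall elasticity is not modelled mechanistically.

## Boyle–Van't Hoff analysis

Osmotic-shift experiments are summarized as BVH plots: normalized volume
$V/V_{iso}$ against normalized inverse concentration $C_{iso}/C_{out}$.
An ideal osmometer falls on the line $y = (1-\nu_b)x + \nu_b$; the
intercept estimates the normalized non-osmotic volume and the line passes
through (1, 1) by construction, a consistency check `fit_bvh_linear()`
reports (`slope + intercept`). Whether to *force* the line through (1, 1)
is a free design choice; the default fits both coefficients and reports
the constraint check, with `through_iso = TRUE` available, because the
free fit surfaces normalization errors the constrained fit would hide.

Linearity itself is the test of ideal-osmometer behavior. The package uses
the standard pure-error lack-of-fit F-test when concentration levels are
replicated, falling back (with a warning) to a quadratic-curvature t-test
otherwise; the procedure is a design choice of this package, since visual
linearity is not a statistic. Power calculations in the tests use
turgor-scale effective tensions (~0.5 N/m) for walled cells: at
protoplast-scale tensions (tens of mN/m) the curvature is genuinely below
a few-percent measurement noise floor, which is exactly why protoplasts
read as ideal osmometers.

`infer_osmolytes()` inverts the ideal-osmometer law for a paired shift on
one cell: with volumes before/after a known change $\Delta C$ of the
medium, $C_1 = \Delta C\,(V_2-b)\,/\,((V_1-b)-(V_2-b))$ and
$N = C_1 (V_1 - b)$. The non-osmotic volume is taken as
$\nu_b V_{iso}$ with the population $\nu_b$ — per-cell $\nu_b$ estimation
is deliberately out of scope. Estimates whose volume change contradicts
the sign of $\Delta C$ are flagged, not discarded.

## GEM nanorheology

Tracks of 40-nm multimeric nanoparticles (100 Hz, 10 s in the reference
protocol) are reduced to a time-averaged MSD per track over all start
points, then a count-weighted ensemble mean (`compute_msd()`). The
averaging scheme, the 10-frame minimum track length, and gap-splitting
are design choices documented here rather than prescriptions; a
`per_track` mode retains the per-track curves for dispersion summaries.

* `fit_deff()` fits the first 10 lags to `MSD = 4 D_eff tau` through the
  origin (no offset). Static localization error of SD $\sigma_{loc}$
  offsets the MSD by $4\sigma_{loc}^2$; with the default 0.03 µm this
  inflates the through-origin $D_{eff}$ by ~3% at cytoplasmic
  diffusivities. It is documented and measurable (`offset = TRUE`), but
  not corrected by default, matching the plain truncated-fit convention.
* `fit_alpha()` takes the log–log MSD slope over lags 2–50 (configurable);
  $\alpha < 1$ is subdiffusion.
* `fit_phillies()` fits the stretched-exponential concentration law
  $D = D_0 e^{-\beta C^{\lambda}}$; with $\lambda$ fixed the problem is
  linear in $\log D$, with $\lambda$ free a Levenberg–Marquardt fit is
  initialized from the $\lambda = 1$ linear solution.
  `phillies_vs_volume()` re-parameterizes via the ideal-osmometer relation
  $C \propto 1/(V-b)$, and `infer_dilution_from_deff()` inverts the
  $\lambda = 1$ law to convert a $D_{eff}$ fold-change into a fractional
  concentration change.

The free-solution reference `stokes_einstein_d0()` defaults to water at
30 °C (η = 7.97 × 10⁻⁴ Pa s): ~13.9 µm²/s for a 40-nm sphere.

## Growth and N/C homeostasis

Volume growth is exponential, driven by biosynthesis scaling with
cytoplasmic volume, and a fixed fraction $f_0$ of new osmotically active
material enters the nucleus:

$$\frac{dV^C}{dt} = \gamma_C V^C,\qquad
  \frac{dV^N}{dt} = f_0\,\gamma_C V^C
  \;\;\Rightarrow\;\;
  \frac{d(N\!/\!C)}{dt} = \gamma_C\,(f_0 - N\!/\!C).$$

The ratio relaxes to $f_0$ at the growth rate with **no feedback and no
free parameters**: the correction rate is $-\gamma_C$, deviations halve
every doubling time, and correcting a large deviation takes
$\log_2(\mathrm{deviation}/\mathrm{tolerance})$ generations
(`generations_to_correct()`). A linear-growth contrast mode corrects
large cells more slowly.

### Estimator design

Following the field's practice, per-cell rates are OLS slopes of $V(t)$
or $N\!/\!C(t)$ over the (default 40-min, 4-min-sampled) window, with
mitotic timepoints excluded by a data-supplied flag. The population
regressions then estimate $\gamma_C$ (rate vs volume) and
$\gamma_{NC}, f_0$ (rate vs ratio; slope and x-intercept).

The *regressor* matters over a finite window. Against the **initial**
value — the convention used on the published plot axes — an exponential's
secant slope inflates $\gamma_C$ by $(e^{\gamma T}-1)/(\gamma T)$ (+13% at
$\gamma T = 0.24$) and deflates $|\gamma_{NC}|$ by the mirror factor.
Against the **window-mean** value the finite-window factors cancel — in
continuous time the secant rate satisfies $\Delta V/\Delta t =
\gamma \langle V\rangle$ exactly — so the mean-regressor estimator is
unbiased. The package defaults to `x = "mean"` and provides
`x = "initial"` for comparability; the tests assert the initial-x bias
against its closed form rather than ignoring it.

## Perturbation scenarios

`simulate_redistribution()` models a nuclear-export block: a scheduled
fraction of the cytoplasmic osmolyte pool moves into the nucleus (linear
ramp by default — the simplest shape consistent with a progressive
effect; fully configurable) while synthesis continues at a modifiable
rate, and the steady state is re-solved at each step. Transfer conserves
total osmolyte amount exactly. By default dry volume moves pro rata with
the solutes, keeping $\nu_b$ matched across the envelope, as observed
experimentally under export block; an option decouples them. In the
buffered limit the N/C ratio tracks the amount ratio: moving 1.4% of the
cytoplasmic pool raises an 8% ratio to 9.28% — a 16% relative increase.

`simulate_uniform_dilution()` models a uniform biosynthesis slowdown by
scaling both pools equally: the amount-ratio N/C is exactly invariant, for
any factor — the model counterpart of the observation that translation
inhibition leaves the ratio unchanged while slowing both growth and
correction proportionally.

One subtlety: at zero surface tension the steady-state balance pins the
cytoplasmic colloid concentration to the external one, so "cytoplasmic
dilution" cannot appear in $C^{Cy}$ in that regime; within this framework
it surfaces only through the tension term (Laplace relaxation as the cell
grows). The experimental dilution signal reflects total crowding,
including components outside the colloid balance, which the steady-state
model does not track.

## Synthetic data: what it does and does not emulate

All pipeline inputs can be generated with fixed seeds:

* **Shift tables** (`gen_shift_dataset()`): lognormal cell-size
  heterogeneity (CV 0.3 — asynchronous-population scale), volumes from
  the single-compartment forward model (exactly the BVH line at zero
  tension), multiplicative lognormal measurement noise (CV 5% — a
  placeholder for the unpublished 3D-segmentation error), isotonic level
  0.4 M-equivalent with shifts 0.2–1.0 M.
* **Tracks** (`gen_brownian_tracks()`, `gen_fbm_tracks()`): Brownian or
  fractional Gaussian increments with *exact* covariance (Davies–Harte
  circulant embedding; $\alpha = 2H$), plus optional static localization
  error (default 0.03 µm). Exact covariance matters: approximate AR
  schemes would bias the $\alpha$-recovery calibration.
* **Cohorts** (`gen_homeostasis_population()`): mothers at the
  equilibrium ratio divide with an asymmetrically placed septum while
  nuclei split evenly, so a daughter receiving volume fraction $a$ is
  born at $N\!/\!C = f_0/(2a)$. The default asymmetry SD of 0.1 was
  derived once, analytically, so that the dispersed cohort's birth-ratio
  SD is threefold the symmetric-division (noise-only) case given 5%
  volume noise: $\sqrt{3^2-1}\cdot\sqrt{2}\cdot 0.05 = 0.2$ CV.
* **Diffusivity tables** (`gen_phillies_dataset()`): the stretched
  exponential law with lognormal noise.

What passing recovery tests on these data shows is that the estimators
are correct *under the model's assumptions* — exponential growth, ideal
osmometry, stationary increments, multiplicative noise. Real data add
adaptation kinetics (glycerol response to hyperosmotic shock — handled
experimentally by acute measurement windows, not modelled here),
segmentation artifacts, tracking errors and heterogeneous particle
populations, none of which the generators emulate.

## Problem sizes

The shipped tests and the acceptance script use 400-cell shift datasets,
500–1000 tracks of 10 s at 100 Hz, and cohorts of 10³–2×10³ cells over
40-min windows — sizes chosen to hold estimator sampling error to a few
percent, comparable to the source study's track and cell counts.
Stochastic assertions use tolerances set from propagated standard errors
at those sizes (≈2.5 SE), fixed before the seeds were run.

## Known limitations

* Steady states only: water/solute flux dynamics and adaptation kinetics
  are out of scope (the growth ODE is the only dynamic element).
* No mechanical wall model; $\sigma^C$ is an effective scalar.
* Per-cell $\nu_b$ is not estimated; osmolyte inference uses the
  population value.
* The $\lambda \approx 1$ ↔ polymer-molecular-weight mapping rests on
  external in-vitro calibrations and is not reproduced.
* Division placement is phenomenological (a truncated-normal volume
  fraction); the polarity biology that causes asymmetric septation is not
  modelled.
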