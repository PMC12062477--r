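---
title: "Model-based design spaces for MSC cultivation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based design spaces for MSC cultivation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mscds)
```

## The problem

Expanding mesenchymal stem cells (MSCs) for cell therapy requires choosing a
seeding density $X_\mathrm{seed}$ and a harvest time $t_h$ so that the
harvested culture meets its quality specifications — enough cells for a dose,
but not so confluent that cell quality degrades. Because growth varies
between wells, operators and cell batches, a single deterministic prediction
is not a safe basis for that choice. `mscds` implements a quality-by-design
workflow that turns a small pre-experiment into a *probabilistic design
space* (DS): the set of $(X_\mathrm{seed}, t_h)$ combinations whose predicted
probability of meeting all specifications is at least a minimum acceptable
risk $\pi$, together with metrics for validating that region against an
independent experiment.

## Growth model

Adherent growth is described by a logistic ordinary differential equation
with two multiplicative penalties on the intrinsic rate:

$$\frac{dX}{dt} = \mu X, \qquad
\mu = \mu_m\,(1 - \varepsilon K_s)\left(1 - \frac{X}{X_m}\right),
\qquad X(24\,\mathrm{h}) = X_0 = \alpha X_\mathrm{seed},$$

where $X$ is the adhesion-cell density (cells cm$^{-2}$), $\mu_m$ the maximum
specific growth rate (h$^{-1}$), $\varepsilon$ the seeding heterogeneity,
$K_s$ a fixed spatial-limitation constant (24.7, from the literature on this
cell system), $X_m$ the saturation density, and $\alpha$ the adhesion ratio.
The clock starts on Day 1 (24 h post seeding), when imaging-based counts
become reliable; all harvest times are expressed in days post seeding and
mapped internally to hours.

Because $\mu$ is affine in $X$, the ODE is a logistic equation with the
closed-form solution implemented in `closed_form_growth()`. The numerical
route (`simulate_growth()`, `lsoda` with `rtol = 1e-8`, `atol = 1e-6`) and
the closed form agree to better than $10^{-6}$ relative error across the
parameter space — a tested invariant. The Monte-Carlo stages therefore
evaluate the closed form, which is vectorized over iterations and times and
roughly three orders of magnitude cheaper than per-iteration integration,
while remaining exactly interchangeable with the integrator. Tolerances were
chosen so that the equivalence test is meaningful rather than vacuous.

Degenerate regimes are represented honestly rather than clipped: if
$\varepsilon K_s > 1$ the effective rate is negative and the density decays
toward zero — `kinetic_params()` flags and warns but does not alter the
value, since silently repairing it would hide a data problem.

## Per-sample inputs from tiled counts

Each well is imaged as an 8 × 8 tiling (64 tiles) of a
15.3 mm × 15.3 mm area. From the per-tile adhesion-cell counts
$N^\mathrm{img}_i$:

* adhesion ratio: $\alpha = \sum_i N^\mathrm{img}_i(\mathrm{Day\,1}) / (S\,X_\mathrm{seed})$,
* seeding heterogeneity: the population standard deviation of the normalized
  Day 1 tile counts, $\varepsilon = \sqrt{\tfrac1{64}\sum_i (N^\mathrm{img}_i/\sum_j N^\mathrm{img}_j - \tfrac1{64})^2}$,
* saturation density: $X_m = 64 \cdot \max(N^\mathrm{img}) / S$, the densest
  tile over all tiles and timepoints scaled to the full area.

Two readings of the imaged area $S$ are plausible — the square tiling area
(2.3409 cm²) or a circle of diameter 15.3 mm (1.8385 cm²). The square
reading is the default because the tiling is described as a square mosaic;
the circle is available by passing `S = pi * (1.53 / 2)^2`. "Day 1" is the
frame closest to 24 h post seeding, required to fall within ±3 h of it: with
a 6-h imaging cadence the frame is unambiguous, and the tolerance only
guards ragged grids. Totals-only data support $\alpha$ and (under an
explicit uniformity flag) $X_m$, but $\varepsilon$ is undefined without
tiles and is refused rather than guessed.

## Growth-rate estimation and model checking

For each sample the package minimizes the residual sum of squares between
the measured total counts and $N(t) = S\,X(t)$ over $\mu_m$ alone
(`fit_sample()`), holding $(\alpha, \varepsilon, X_m)$ fixed at their means
over the fitting dataset — the convention of the workflow; a per-sample and
a per-density mode exist for sensitivity work. The optimizer is Nelder–Mead
with an iteration cap of 5000 and objective tolerance $10^{-10}$; the
objective is smooth and unimodal in $\mu_m$ for this model, so the default
start of 0.03 h$^{-1}$ (the order of literature values) is uncritical.
$\mu_m$ is unconstrained in sign; negative optima are reported, not clipped,
because they signal degenerate data. Non-convergence flags the fit and keeps
it, so that one pathological well cannot abort a study.

The estimate is the mean of the per-sample rates; its spread is the sample
standard deviation (`aggregate_fits()`). Model adequacy is checked per
seeding density with the NRMSE — RMSE over all samples and timepoints
divided by the group's measured count range, in percent — against the
conventional 10 % threshold (`validate_model()`).

## Prediction interval

Uncertainty in $\mu_m$ enters the DS through a two-sided Student-t
prediction interval,

$$\mu_m^\mathrm{UP/LO} = \bar\mu_m \pm t_{(0.975,\,n-1)}\, s \sqrt{1 + 1/n},$$

with $n$ the number of fitted samples (never the number of timepoints). A
prediction interval — wider than a confidence interval by the $\sqrt{1+1/n}$
factor — is the right object because the question is where a *future
sample's* growth rate will fall, not where the mean is. With the reference
values $\bar\mu_m = 2.76\times10^{-2}$ h$^{-1}$, $s = 1.46\times10^{-3}$,
$n = 18$:

```{r}
mu_m_prediction_interval(list(mean = 2.76e-2, s = 1.46e-3, n = 18))
```

## Monte-Carlo limits and the probability map

The remaining variability — operator and cell-level variation in
$(\alpha, \varepsilon, X_m)$ — is propagated by resampling the *empirical*
per-sample measurements rather than a fitted distribution: `sample_theta()`
draws $M$ rows with replacement from the pool. The default draws each
column independently, mirroring per-parameter random selection from the
measurement tables; a `joint` mode draws whole per-sample triples and
preserves within-sample correlations. Both are defensible; the mode is
recorded in the output so a run is self-describing.

For each $\theta$ row and seeding density, two trajectories are produced —
one at $\mu_m^\mathrm{UP}$, one at $\mu_m^\mathrm{LO}$ — and evaluated at
all grid harvest times from the same trajectory (one parameterization, one
curve). The predicted quality attributes are $N = S\,X$ and $P = X/X_m$
using *that row's own* $X_m$, so an iteration is internally consistent;
since the model forbids $X > X_m$, $P$ cannot exceed 1.

The probability map is, per condition,

$$h(x, t) = \frac{100}{M} \sum_{i=1}^M
I\left(y_i\rvert_\mathrm{UP} \in A \;\wedge\; y_i\rvert_\mathrm{LO} \in A\right),
\qquad A = \{(N, P) : 5.0\times10^4 \le N \;\wedge\; P < 0.8\},$$

i.e. an iteration succeeds only when **both** limits satisfy the
specification — conservative by construction. The reference
(`mode = "point_estimate"`) uses the mean rate alone. Because $A$ is an
interval in $X$ and $X$ is monotone in $\mu_m$, the interval-based
probability can never exceed the point-estimate one at a shared draw, so the
interval-based DS is nested inside the reference DS — both are tested
properties. The DS is the inclusive level set $h \ge \pi$; the printed
inequalities ($\ge N_\mathrm{min}$, $< P_\mathrm{max}$, $\ge \pi$) are
honoured exactly, with no smoothing or interpolation of the surface.

The default grid spans 1500–4500 cells cm$^{-2}$ in steps of 375 and
Days 1–9 every 6 h — 9 × 33 = 297 conditions; validation uses the three
experimental densities (99 conditions).

Convergence of the $M = 1000$ iterations is diagnosed with the relative
standard deviation of the Monte-Carlo mean of the final cell number,
estimated by batch means: split the iterations into 10 batches, then
$100 \cdot (\mathrm{sd}(\text{batch means})/\sqrt{10}) / \text{mean}$. This
estimates the relative standard error of the mean, the quantity the
workflow's reference bound of 0.2 % refers to; the diagnostic is reported
and warned about, never enforced.

## Validation metrics

Validation compares $h$ with the experimental probability
$h^\mathrm{exp}$ — the percentage of validation samples at a condition whose
measured $(N^\mathrm{exp}, P^\mathrm{exp})$ satisfy $A$. Measurements are
matched to grid cells exactly; off-grid conditions are an error, never
snapped. $P^\mathrm{exp}$ uses each sample's own measured $X_m$ by default
(each well is its own reference for confluency); a global-mean mode is
available. Crossing $h$ and $h^\mathrm{exp}$ at $\pi$ gives four categories
(correctly/incorrectly identified feasible/infeasible) and three ratios:
precision-like $R_1$, recall-like $R_2$, specificity-like $R_3$. Ratios
with empty denominators are reported as missing — an empty DS yields
$R_1 = \mathrm{NA}$, not a fake 0 or 1. `permutation_study()` repeats the
whole chain with each experiment group in turn as the pre-experiment, across
a set of $\pi$ values; with a noisy pre-experiment the DS can be legitimately
empty at $\pi = 90$, and is reported as such.

## What the synthetic generator emulates

`generate_experiment()` produces complete studies with the structure the
method assumes: 3 seeding densities × 6 replicates × 3 operators, 64-tile
counts every 6 h from Day 1 to Day 9. Study-design values are fixed at the
reference conditions (densities 1500/3000/4500 cells cm$^{-2}$,
$\mu_m \sim \mathcal N(2.76\times10^{-2}, 1.46\times10^{-3})$ h$^{-1}$,
$S = 2.3409$ cm², $K_s = 24.7$). The quantities a real study measures rather
than sets were chosen once, at values a practitioner would call realistic
for healthy MSC expansion, such that the resulting design spaces show the
expected structure (feasible windows of roughly half a day to a day,
starting near Day 8 at 1500 cells cm$^{-2}$ and near Day 6 at 4500):

* adhesion ratio $\alpha \sim$ Beta(mean 0.75, concentration 100) — most
  seeded cells attach, with a few percent well-to-well spread;
* saturation density $X_m \sim \mathcal N(45000, 1000)$ cells cm$^{-2}$,
  truncated positive;
* Day 1 tile allocation: symmetric Dirichlet–multinomial with concentration
  45, giving a realized heterogeneity $\varepsilon \approx 0.002$–0.003 —
  the level the feasible-window endpoints imply through the logistic
  crossing times; $\varepsilon$ is *emergent* — the generator records the realized
  value as truth, mirroring how the workflow measures rather than sets it;
* counting noise: multiplicative lognormal with CV 5 % on post-Day 1 totals
  (Day 1 counts are the allocation itself, so the adhesion ratio is
  recoverable to rounding). A per-tile Poisson mode exists behind a flag.

Growth propagation uses the closed-form model driven by each sample's
realized Day 1 state — deliberately an "inverse crime" at the total-count
level, because the package's recovery tests are about the estimation
machinery, not about model misspecification. One structural feature of real
tiled counting *is* modelled: tiles have a local capacity $S/64 \cdot X_m$,
so locally dense tiles saturate first and the maximum-tile estimator of
$X_m$ is consistent once a culture matures. Without local saturation that
estimator is strongly biased low for wells that never reach global
confluency, and the parameter pools degrade in a way real data do not show.

What the generator does **not** emulate: image segmentation error structure,
spatial correlation between neighbouring tiles, nutrient/metabolite
dynamics, lag phases, or genuine model misspecification of the growth law.
Passing tests on synthetic data therefore demonstrate that the chain of
estimators and decisions is correct and well-calibrated under the model's
own assumptions — they cannot certify the growth law itself against a real
laboratory system.

## Numerical choices and problem sizes

* Integrator `lsoda`, `rtol = 1e-8`, `atol = 1e-6`; closed form elsewhere.
* Nelder–Mead, 5000 iterations cap, objective tolerance $10^{-10}$,
  start 0.03 h$^{-1}$.
* One shared $\theta$ draw per map; a seed argument makes every stochastic
  stage bit-reproducible, and identical seeds give byte-identical exports.
* Ties at thresholds: $N \ge N_\mathrm{min}$ and $h \ge \pi$ inclusive,
  $P < P_\mathrm{max}$ exclusive.
* The test suite exercises the full 297-condition grid at $M = 1000$ where
  the claim concerns the study scale (convergence, nestedness), and smaller
  $M$ (200–500) or replicate counts where the claim is structural; the
  end-to-end conservatism check pools 20 replicated studies at $M = 500$.

## Known limitations

Only the two-dimensional $(X_\mathrm{seed}, t_h)$ case is implemented. The
confluency attribute inherits all the uncertainty of the max-tile $X_m$
estimator. $K_s$ is treated as a known constant; no uncertainty is
propagated through it. The validation ratios are reported without
confidence intervals, matching the workflow they summarize.
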