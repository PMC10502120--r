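---
title: "Inferring in situ growth phases from metagenomic time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring in situ growth phases from metagenomic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseflow)
```

## The model

`phaseflow` treats the gut (or any quasi-batch flow-through ecosystem)
as a collection of populations whose internal dynamics follow logistic
growth, sampled at its steady-state endpoint once per stool. The
deterministic skeleton is

$$\frac{dx}{dt} = r\,x\Bigl(1 - \frac{x}{K}\Bigr),$$

with maximal growth rate $r$ (per unit time), carrying capacity $K$
(abundance units; biologically, a dietary/host-substrate niche size)
and initial abundance $x_0$. The closed form is evaluated as
$K / (1 + \frac{K - x_0}{x_0} e^{-rt})$ so the exponential never
overflows. Stochasticity enters as multiplicative white noise (Itô),

$$dx = \Bigl[r\,x\bigl(1 - x/K\bigr) - H\,x\Bigr]\,dt
      + \sigma\,x\,dW,$$

where $\sigma$ is the noise magnitude and $H$ an optional harvest
(dilution) rate. With $H < r$ the stable point shifts from $K$ to
$K(1 - H/r)$ — proportional removal is equivalent to a smaller
effective niche, which is why defecation rate does not change the
phase logic, only the stable abundance.

### Phase geometry

Growth phases are defined from the second derivative of the
deterministic curve (the growth acceleration),

$$\frac{d^2x}{dt^2} = r^2\,x\Bigl(1 - \frac{x}{K}\Bigr)
                      \Bigl(1 - \frac{2x}{K}\Bigr).$$

The curve has one positive peak (at $x = K(3-\sqrt3)/6 \approx 0.21K$)
and one negative trough (at $x \approx 0.79K$). The four boundary
times are the crossings of the half-maximum ($s_1, s_2$) and
half-minimum ($s_3, s_4$) levels; lag is merged into acceleration
because both show the same rate–abundance relationship. Windows are
half-open with ties to the later phase: acceleration $t < s_2$,
mid-log $[s_2, s_3)$, deceleration $[s_3, s_4)$, stationary
$t \ge s_4$ — they tile the time axis with no gaps.

A note on the prefactor: the analytically exact second derivative
carries $r^2$; one sometimes sees the same expression written with a
different positive prefactor. The crossing *abundances* are roots of
the scaled shape $u(1-u)(1-2u)$, $u = x/K$, so the boundary times are
provably invariant to any positive rescaling of the acceleration
curve. `phase_boundaries()` exposes the prefactor argument, and the
test suite asserts the invariance directly.

Root finding brackets each crossing from the analytic crossing
abundances and refines on the time axis with `uniroot`, verifying
$|f| < 10^{-10}\,a_{\text{peak}}$. Curves with $x_0 \ge K/2$ start
past the acceleration peak and are refused (the forward crossings do
not all exist); $x_0$ above the *first* crossing abundance merely
makes $s_1$ negative, which is harmless because lag and acceleration
are merged anyway.

## Simulator numerics

The ensemble integrator is Euler–Maruyama with `dt = 0.01` by default
(`n_steps = 100` per unit time), time span 1–100, 100 iterations:

$$x_{j+1} = x_j + \bigl[r x_j (1 - x_j/K) - H x_j\bigr] dt
           + \sigma x_j \sqrt{dt}\, Z_j .$$

Design choices:

* **Scheme.** Plain Euler–Maruyama; first-order convergence is
  checked by step-halving in the tests, and `n_steps` is a
  configuration knob. Configurations with $r\,dt > 0.5$ are refused
  outright rather than silently overshooting.
* **Positivity.** Paths are clamped at $10^{-12}$ (absorbing at
  effective zero). At the default noise levels and $x_0 = 1$ the clamp
  is essentially never active; reflecting schemes would complicate the
  noise law for no visible benefit.
* **Noise on the carrying capacity.** The stochastic-$K$ variant
  perturbs $k_j = K + \sigma K \sqrt{dt} Z_j$ freshly at each step
  (white noise on the niche size, floored at $10^{-6} K$) while the
  abundance update itself stays deterministic. The temporal structure
  of niche fluctuation is a modelling choice; independent-per-step is
  the least structured option and preserves the sigmoidal shape and
  the per-phase correlation signs, which is what it is used to
  demonstrate.
* **Reproducibility.** One ensemble seed deterministically spawns one
  sub-seed per iteration, so path $i$ is bit-identical regardless of
  `n_iter`, and the whole ensemble is reproducible from its
  configuration.

Within a phase window, `phase_window_correlation()` computes a Pearson
correlation between $x(t_j)$ and the forward difference
$x(t_{j+1}) - x(t_j)$ *per iteration* and leaves summarising (median,
quantile band) to the caller. Pooling points across iterations before
correlating is statistically defensible too; per-iteration was chosen
because it keeps iterations exchangeable and gives a distribution of
correlations rather than one number — the pooled variant is a
one-liner on the returned matrix if wanted. Correlations are computed
for all four windows even though the stationary window's delta-based
correlation is dominated by regression to the mean (systematically
negative) rather than by growth; sign expectations are only asserted
for acceleration (positive) and deceleration (negative), with mid-log
near zero at moderate noise. At high noise ($\sigma \sim 1$) these
signatures degrade and no sign is guaranteed — this mirrors how real
biological noise can override the signal.

## Longitudinal statistics

* **CLR transform.** Per sample: $\ln(c_i + p)$ minus the sample mean
  of $\ln(c_j + p)$ over *all* taxa in the table (abundance filtering
  happens after transformation, so the geometric-mean reference is
  stable). The pseudocount $p$ defaults to 0.5 — the conventional
  half-count for zero handling — and is configurable. Output columns
  sum to zero by construction.
* **Deltas.** Consecutive-sample changes $x(t_{n+1}) - x(t_n)$ are
  kept only when the day gap is *strictly* below 3 days; longer gaps
  are dropped, never interpolated. Days are integers supplied by the
  metadata (0-based from the first sample).
* **Per-taxon regression.** Ordinary least squares of CLR abundance
  (response) on log2(PTR), over days where both are available; a
  taxon needs strictly more than 5 matched points. The classifier
  consumes only the slope *sign* and its significance, both of which
  are orientation-free; the cohort-level taxonomy-covariate model
  (`covariate_adjusted_regression()`) uses the reverse orientation
  (log2(PTR) response, group indicators as covariates) because there
  the PTR is the outcome being explained across taxa. Both
  orientations are deliberate and documented rather than reconciled.
* **Multiple testing.** Benjamini–Hochberg within each donor across
  that donor's eligible taxa — the donor is the inference unit, so it
  is the FDR family. Donor-level p-values (from the mean-vs-mean
  regression across taxa) are combined across donors with Fisher's
  method, $-2\sum\ln p_i \sim \chi^2_{2k}$.
* **Stationarity screen.** An augmented Dickey–Fuller test with
  constant and trend, lag order selected by AIC up to
  $\lfloor (n-1)^{1/3} \rfloor$ (models compared on a common sample),
  p-values interpolated from the standard Dickey–Fuller tau table for
  the constant+trend case and clipped to $[0.01, 0.99]$. A
  *significant* p rejects the unit root, so `p < 0.1` flags the series
  as stationary. The implementation is self-contained and is validated
  in the tests by its operating characteristics: $\ge 95\%$ power
  against an AR(1) with coefficient 0.5 at $n = 300$, and a false-flag
  rate near the nominal 10% on random walks.

## The classifier

Decisions are made in a fixed order per taxon, from its mean log2(PTR)
and its FDR-adjusted regression:

1. mean log2(PTR) below the stationary threshold → **stationary**;
2. $q < \alpha$ and slope $> 0$ → **acceleration**;
3. $q < \alpha$ and slope $< 0$ → **deceleration**;
4. otherwise → **midlog_or_indeterminate**.

The threshold default (0.358) is the mean log2(PTR) of in vitro
stationary-phase *E. coli* — an empirical constant carried in the
configuration object, never hard-coded in the rules, because it is
admittedly coarse (one organism, and PTR scales are only roughly
comparable across taxa). The stationary rule takes precedence over the
slope rule: a sub-threshold taxon with a significant slope is still
called stationary but flagged
(`significant_slope_below_threshold`) so the conflict is visible. The
null outcome is deliberately *not* labelled "mid-log": with tens of
time points the slope test is underpowered, and an indeterminate call
may well be a missed acceleration/deceleration.

## The synthetic-data generator

`donor_spec()` emulates a dense stool-bank style donor series: 3–5
collection days per week (day gaps of 1–3 days, so the delta gate is
exercised), 60 time points by default, 12 taxa (three per phase) with
growth rates 0.8/1.2/1.6, $K = 100$, sequencing depths 5k/10k/20k,
Poisson counts around `mean_depth * x / K`, and a 10% per-cell PTR
missingness. Each stool day reads one fresh stochastic path of the
taxon at a time drawn uniformly from the taxon's fixed true-phase
window; the stationary window extends one active-growth span
($s_4 - s_1$) beyond $s_4$, reflecting the premise that stool samples
the steady-state endpoint, well past the deceleration trough.

The replication-rate map is affine in the *normalized effective growth
rate* $g = \frac{dx/dt}{rK/4} \in [0, 1]$:

$$\log_2\mathrm{PTR} = b_0 + b_1\,g + \varepsilon,
  \qquad \varepsilon \sim N(0, 0.06^2).$$

Three choices here deserve justification:

* **Absolute rate, not per-capita rate.** Under the logistic model the
  per-capita rate $r(1 - x/K)$ *decreases monotonically* with
  abundance in every phase, so a per-capita coupling would give
  acceleration-phase taxa *negative* PTR–abundance slopes — the
  opposite of what both the model's expected phase relationships and
  in vitro growth curves show. The absolute rate $rx(1-x/K)$ rises
  with abundance before $K/2$, falls after, and vanishes at
  saturation, which reproduces the
  positive/null/negative/null signature across
  acceleration/mid-log/deceleration/stationary.
* **Rate from the curve position, not from the realized noisy state.**
  Replication status is a property of where the population sits on its
  growth trajectory. If the map instead used the drift at the realized
  noisy abundance, every downward fluctuation at stationarity would
  imply a burst of regrowth, manufacturing a strong negative
  PTR–abundance association in stationary phase — in vitro stationary
  populations show a *null* association. The stochastic abundance
  fluctuation is therefore treated as ecological/observational noise
  that does not feed back into the replication machinery.
* **Calibration to the two in vitro anchors.** $b_0$ (log2 PTR at zero
  growth) defaults to 0.30, the deep-stationary floor observed in
  vitro, and $b_1$ is calibrated per taxon so the *mid-log window
  mean* equals the mid-log anchor 1.25. The stationary-window mean
  then lands at $\approx 0.33$ — between the floor and the
  early-stationary anchor 0.358, and below the classifier threshold.
  Setting $b_0$ *equal* to the threshold would be self-defeating: the
  ground-truth stationary taxa would be calibrated to sit exactly on
  the decision boundary, and their classification would be a coin
  flip by construction. Real classified-stationary taxa sit visibly
  below the threshold, which is what the generator reproduces.
  `ptr_noise_sd = 0.06` matches the in vitro stationary spread
  (0.059); $\sigma = 0.2$ is the abundance noise level that
  reproduces human-like correlation spreads (the ensemble simulator
  itself defaults to $\sigma = 0.1$, the representative simulation
  setting).

What the generator does *not* emulate: read-level sequencing (no
FASTQ, no coverage profiles — PTR values are drawn directly),
between-taxon ecological interactions, compositional coupling beyond
the shared CLR denominator, within-day autocorrelation of the PTR
estimator, or taxon-specific PTR scale differences. Passing the
recovery tests therefore shows that the pipeline correctly inverts
*this* generative model at realistic sampling density and noise — it
does not certify performance on real data, where the PTR–growth map
is unknown and varies by organism.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: the simulation grid
$r \in \{1,2,3\} \times K \in \{10,100,1000\}$ at $\sigma = 0.1$ with
100 iterations and `dt = 0.01`; 100-path ensembles for the
regression-to-the-mean and noise-scaling properties; 20 random
parameterizations for the boundary-geometry oracle (agreement to
$10^{-6}$ time units against a Richardson-extrapolated
finite-difference scan); harvested equilibria to 0.1%; synthetic
donors at 20/60/120 time points with the default 12 taxa; and 1,000
random p-vectors for the exact BH comparison. These sizes keep the
default test run in the tens of seconds while leaving the Monte-Carlo
assertions far from their thresholds (e.g. the stationary
negative-delta fraction is 100/100 where 95/100 is asserted).

## Known limitations

* The phase windows come from the *deterministic* curve; under strong
  noise the realized acceleration geometry of individual paths
  differs, and at $\sigma \gtrsim 1$ the phase signatures vanish
  entirely.
* PTR values are treated as roughly comparable across taxa; no
  genome-size or C-period conversion is attempted.
* The ADF screen's p-values are table-interpolated and clipped to
  $[0.01, 0.99]$; it is a screen, not a precise test.
* No alternative growth laws (Gompertz, Baranyi), no multi-species
  coupling, and no inference of $(r, K, \sigma)$ from observed
  trajectories — simulation is forward-only, and the classifier works
  from summary statistics, not trajectory fits.
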