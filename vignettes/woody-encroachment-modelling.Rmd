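---
title: "Modelling evergreen woody-plant distributions and encroachment on synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evergreen woody-plant distributions and encroachment on synthetic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpeniche)
```

## The problem

Woody plant encroachment (WPE) — the expansion of trees and shrubs, notably
eastern red cedar, into grasslands — is a major driver of land-cover change
in the central Great Plains. `wpeniche` implements a landscape-scale analysis
pipeline for (i) mapping evergreen woody cover from radar backscatter and
optical vegetation-index layers with knowledge-based decision rules, (ii)
detecting encroachment as the two-date overlay of evergreen maps, and (iii)
modelling and *anticipating* the distribution of evergreen cover and of
encroachment with presence–background maximum-entropy niche models, selected
from large candidate grids and transferred, with no extrapolation permitted,
to an independent region.

Because the satellite inputs of such an analysis are large and external, the
package ships a seeded synthetic-landscape generator that reproduces the
statistical structure the analysis assumes. Every stage — classification,
terrain derivation, sampling, model fitting, selection, transfer — runs
offline against landscapes whose true suitability surface is known, so the
whole pipeline is testable end to end.

## Land-cover classification

A pixel is classified as forest iff all four rules hold:
$-19 \le HV \le -7.5$ dB, $0 \le HH-HV \le 9.5$ dB,
$0.2 \le HH/HV \le 0.95$ (ratio of the dB values), and
$NDVI_{max} > 0.7$. Within forest, a winter mean NDVI above 0.4 marks
evergreen canopy. Closed ranges are inclusive at their printed bounds and
the NDVI thresholds are strict; that typography is deliberate and pinned by
unit tests. The ratio rule is applied to the dB-scale values as given — no
linear-power conversion. Nodata propagates through every rule: a pixel is
classified only when all bands are valid; we do not gap-fill.

A WPE pixel holds evergreen forest at the second date and not at the first.
Forest loss and persistent forest are both 0.

## Terrain and distance predictors

Slope and aspect use Horn's 8-neighbour weighted finite differences, the
method behind common GIS terrain tools; aspect is reported as the azimuth of
the downslope direction, clockwise from north in $[0, 360)$, with flat cells
assigned 0. Ruggedness is the terrain ruggedness index: the mean *absolute*
elevation difference between a cell and its eight neighbours (signed
differences average towards zero and carry no information). Distance rasters
are exact Euclidean distance transforms (two-pass separable algorithm),
cell-centre to cell-centre in metres, verified against brute-force
nearest-source search in the test suite. Edge cells of the derivative
layers are nodata.

## The maximum-entropy model

The model is the Gibbs distribution over background cells
$q_\lambda(x) = e^{\lambda \cdot f(x)} / Z_\lambda$, fitted by minimising the
penalized negative presence log-likelihood

$$\ell(\lambda) = -\frac{1}{m}\sum_{i\in\text{presences}} \lambda\cdot f(x_i)
  + \log Z_\lambda + \sum_j \beta_j |\lambda_j|,$$

a convex objective solved with accelerated proximal gradient descent
(FISTA) with backtracking, to a subgradient tolerance of $10^{-6}$ or 500
iterations. Features are the five Maxent classes — linear, quadratic,
pairwise product, threshold and hinge — built on predictors scaled to
$[0,1]$ by the background range, with threshold/hinge knots at background
quantiles (50 by default; pipeline runs use fewer, see below). Per-feature
penalties $\beta_j$ follow the published Maxent defaults interpolated by
presence count, scaled by the feature's presence-sample standard deviation
over $\sqrt{m}$, and multiplied by the user's regularization multiplier, so
the multiplier grid {0.3, 0.5, 0.75, 1, 3, 5} means the same thing it means
in Maxent. With no informative features the fit returns the uniform
distribution — the maximum-entropy solution under no constraints.

Raw output is $q_\lambda$ (summing to one over the background, or
renormalized over a prediction region for the AICc likelihood); suitability
maps use the Maxent 3.4 cloglog transform
$1 - \exp(-e^{H} q_\lambda(x))$ with $H$ the entropy of the fitted
distribution. Prediction clamps features to the background support; strict
no-extrapolation masking is the transfer module's job, not the predictor's.

The fit is validated against independent oracles rather than another
implementation: a fine grid search over $\lambda$ on small linear-feature
problems, coefficient recovery from data simulated under a known Gibbs
density, and the degenerate uniform case.

## Candidate grids and ordered selection

A candidate is a feature-class combination (31 non-empty subsets of the five
classes), a regularization multiplier (6 values), and a predictor subset
(all subsets of size at least two). The grid sizes are
$186\,(2^V - 1 - V)$: 4836 candidates for $V = 5$ predictors and 22,320 for
$V = 7$. Enumeration is always exact; evaluation may run on a configurable
subsample for desk-scale work.

Selection proceeds in order. (1) *Significance*: a bootstrap partial-ROC
test (E = 10%, 500 replicates by default; candidate screening in pipeline
runs uses fewer) comparing the partial AUC of sensitivity versus proportion
of area predicted present, restricted to sensitivity $\ge 0.9$, against the
chance diagonal on the same domain; candidates keep only if p < 0.05. The
p-value is reported in the bias-corrected form $(1 + \#\{ratio \le 1\}) /
(reps + 1)$ so it is never exactly zero. (2) *Performance*: the omission
rate of the evaluation half at the threshold given by the E-percentile
(empirical, type-1) of suitability at calibration occurrences must be
strictly below 10%. (3) *Parsimony*: among survivors, models within 2 AICc
units of the minimum are "best", with AICc computed from the
region-normalized raw output at occurrence cells and $k$ = the number of
nonzero coefficients. Following the kuenm workflow, each candidate is fitted
twice: on the calibration half for stages 1–2, and on the full occurrence
set for AICc and for the final, transferable model. Ties order
deterministically by (AICc, k, candidate index). An empty best set is a
reported outcome, not an error — with a hard 10% omission gate on an
exchangeable 50/50 split, omission hovers near 10% by construction and
seed-level all-fail events do occur; the full grids escape this through
sheer candidate diversity, and reduced grids inherit a nonzero risk of an
empty best set.

Best-model predictions combine as a cellwise median ensemble.

## Truncated transfer

Transfer to an independent region is range-truncated per variable: any cell
where a model predictor falls outside the [min, max] observed over the
calibration region is masked to nodata ("no predictions made under
extrapolative conditions"), implemented as hard masking, not clamping.
Independent occurrences on masked cells are dropped from the final
evaluation and their count reported. The final evaluation applies the same
partial-ROC statistic (E = 10%, 500 replicates) to the truncated projection.

## The synthetic landscape

The generator emulates, on one projected 30 m grid:

* **Terrain** — Gaussian-filtered white noise (kernel sd 5 cells by
  default) rescaled exactly onto the configured elevation range; a smooth,
  strongly autocorrelated surface.
* **Streams** — downhill walks with jittered steepest descent, started
  round-robin across vertical bands from upper-elevation cells, each
  segment of moderate length, until the target density (2% of cells by
  default) is met; the final walk is truncated at the target. Banded starts
  and bounded segments keep the network space-filling at region scale, as
  real drainage is — early designs without them occasionally produced
  county-sized regions with no streams at all, which no Kansas landscape
  exhibits.
* **Cover truth** — true suitability is the inverse logit of a quadratic in
  scaled elevation plus a linear term in distance-to-stream (km). The
  defaults (intercept 0.5, elevation 0, elevation² −8, distance −3) put
  peak suitability at intermediate elevations near streams and give the two
  effects comparable realized magnitude: the elevation field's sd on the
  scaled axis is about 0.3, so the quadratic needs a larger coefficient
  than the distance term to matter equally across the landscape. Evergreen
  cover samples Bernoulli(suitability) inside many small clustered patches
  (12 patch seeds per 1000 cells, radius 1–3 cells, placed uniformly);
  patch placement is environmental noise, so the effective sample size for
  the suitability signal is the patch count, and the patch statistics are
  chosen to mirror the dense, fine-grained red-cedar patchiness of the real
  landscapes (thousands of occurrence pixels per county). Deciduous patches
  complete the forest map; second-date evergreen adds cells with
  probability increasing in suitability and decaying exponentially
  (150 m scale) with distance to the first-date extent; no clearing is
  simulated.
* **Sensor bands** — drawn strictly inside the forest decision envelope for
  forest cells and outside it for others, with winter NDVI separating
  evergreen from deciduous, so the classifier recovers truth exactly at
  zero label noise; a configurable label-noise fraction flips cover regimes
  to probe robustness.

What the generator does *not* emulate: SAR speckle and radiometric realism,
phenological time series, cloud or terrain-shadow artifacts, mixed
deciduous–evergreen pixels, and the 25 m to 30 m resampling of the real
radar grid. Tests passing on these landscapes therefore demonstrate the
correctness of the algorithms and the recoverability of known signal — not
classification accuracy on real imagery.

## Study sizes and numerical choices

Pipeline runs in the package's tests and acceptance script use a
144 × 96-cell landscape (a calibration western half and a test eastern
half), 8000 random casts per region, 1500 background cells, 8
threshold/hinge knots, 60 partial-ROC replicates during candidate screening
and 500 in final evaluations, and a reduced candidate grid of five
feature-class codes (lq, t, h, lqth, lqpth) crossed with all six
multipliers and all predictor subsets of {elevation, aspect, distance to
creek} — 120 candidates. Aspect serves as the irrelevant distractor; it is
nearly uninformative by construction, which is exactly what a recovery
experiment wants in a negative control. The structure-recovery study asks
whether the selected best set contains a model using both generative
predictors and whether the truncated transfer validates significantly on
the held-out half.

Numerical details worth knowing: degenerate (constant-over-background)
feature columns are dropped before fitting; feature sds in the penalty are
floored at 0.05 to avoid unpenalized near-constant features; the FISTA
momentum restarts on any objective increase; partial-ROC curves are
evaluated on 100 thresholds spanning the prediction's value range, and a
replicate whose restricted curve has fewer than two points (a model with no
high-sensitivity domain) contributes no ratio; `quantile(type = 1)` keeps
the omission threshold an order statistic, hence reproducible across
platforms.

## Known limitations

The omission filter's boundary behaviour (above) means reduced grids can
return empty best sets on unlucky splits. The partial-ROC bootstrap
measures resampling variability only, so its null rejection rate is close
to, but not exactly, the nominal level. AICc on presence data compares
candidates, it does not validate absolute fit. And the synthetic
suitability is logistic in its predictors while the Gibbs model is
log-linear in its features, so even a perfectly selected model recovers the
true surface only approximately — which is the realistic situation.
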