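---
title: "Surrogate modeling and multi-response optimization of NLC formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modeling and multi-response optimization of NLC formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlcoptim)
```

## The problem

Nanostructured lipid carriers (NLCs) deliver a plant extract through the
skin, and their quality is summarized by four responses: hydrodynamic
particle size Y1 (nm), polydispersity index Y2 (PDI, dimensionless,
0–1), zeta potential Y3 (mV, stored signed), and entrapment efficiency
Y4 (%EE of the marker phenolic, 5-O-caffeoylquinic acid). Four
composition factors drive them: solid lipid content X1 (wt%), liquid
lipid content X2 (% of total lipid), emulsifier content X3 (wt%) and
extract loading X4 (wt%). `nlcoptim` implements the computational chain
that turns a 30-run designed experiment over these factors into an
optimized formulation: design generation, a neural-network surrogate of
the response surfaces, weight-based and behavioral variable importance,
desirability-based multi-response optimization, release-kinetics model
selection, and the assay arithmetic (%EE, HET-CAM irritation scoring).

## Design space

The design is a rotatable central composite design (CCRD): a 2^4
factorial cube at coded levels ±1, eight axial points at ±α with
α = (2^4)^(1/4) = 2 (rotatability: α^4 equals the number of factorial
points), and six center replicates — 30 runs. Coded and actual units are
linked by the affine transform x = (X − X₀)/ΔX with centers
(6.75, 30, 3.5, 1.375) and steps (3.25, 15, 1.5, 0.625).

The extract factor's center and step are stored exactly (1.375 and
0.625) even though design tables round its levels to two decimals (0.13,
1.38, 2.63): with the rounded levels the coded transform is internally
inconsistent, so the package treats the rounded values as display only.
The packaged dataset (`nlc_study_data()`) stores the exact actuals, which
is why the fixture's coded design equals the generated CCRD exactly as a
multiset — a property the test suite asserts. Zeta potentials are stored
as signed mV values, never magnitudes. Run-order randomization is
available through `shuffle_seed`; the default is the deterministic
canonical order (factorial, axial, center) because the packaged dataset
preserves its published row order.

## The surrogate network

The surrogate is a 4-9-9-4 feed-forward network: two hidden layers of
nine tanh units and a linear output layer shared by all four responses.
The hidden transfer function is `tanh_half(z) = tanh(0.5 z)`, i.e. the
hyperbolic tangent applied to half the pre-activation — the convention
under which the packaged published coefficients reproduce the reported
predictions.

**Input units.** The published coefficients are applied to *actual*
units, not coded units. This was a genuinely open reading; the package
resolves it empirically: under actual-unit inputs every hidden unit's
pre-activation spans both signs across the corners of the design box
(asserted in the tests), whereas under coded inputs units with large
biases (e.g. +18.45, +14.92) would be saturated at +1 everywhere, making
those units useless constants. Networks carry an `input_space` flag so
both conventions remain testable, and `predict_responses()` converts
through the coded transform when asked.

**Training.** The fitting algorithm used originally is commercial and
unspecified, so the trainer is authored here with choices that are
robust for 24 training rows: full-batch BFGS on the summed squared
error with analytic backpropagation gradients; per-column input
standardization and per-response response standardization (the responses
span orders of magnitude — hundreds of nm versus a 0–1 PDI), folded back
into the outer layers after fitting so the returned network maps actual
units to response units directly; multi-restart with seeded
small-uniform initialization in (−0.5, 0.5); restart selection by
held-out RMSE on standardized responses when a held-out set exists,
training RMSE otherwise, ties broken by training loss, then restart
index. No regularization is applied by default and held-out folds are
used for reporting and restart selection only, not for early stopping.
Replicate means are fitted unweighted (the dataset reports means);
`weight_by_sd = TRUE` switches to 1/SD² precision weighting. One network
is fitted jointly to all responses by default, matching the shared
hidden layers of the published equations; `responses = "Y1"` fits a
per-response network instead.

**Fit report.** Per response and partition the report gives the error
sum of squares, RMSE = sqrt(SSE/n), mean absolute deviation, R², and the
Gaussian negative log-likelihood at the maximum-likelihood variance,
(n/2)(log(2π·SSE/n) + 1). That likelihood convention is pinned by a test:
from SSE = 9980.6204 at n = 24 it reproduces RMSE = 20.3926 and
−logLik = 106.4187 exactly as reported for the particle-size training
partition. K-fold cross-validation (`nn_crossvalidate()`, K = 5) gives
the 24/6 train/test partitions of the original workflow.

## Variable importance

`garson_importance()` implements Garson's connection-weight algorithm,
extended to two hidden layers by chaining per-layer normalized absolute
weights along every input→output path; percentages sum to 100 per
response, and the implementation is tested against an exhaustive
path-enumeration oracle on one-hidden-layer networks.
`permutation_importance()` is the behavioral cross-check: the mean
increase in squared prediction error when an input column is permuted.

A documented limitation, measured on the published network: the two
methods disagree there (weight-based: X4 > X3 > X1 > X2 for most
responses; permutation: X3 > X1 > X2 > X4 for particle size). Garson's
algorithm on an actual-units network is input-scale-dependent — the
extract factor spans only 0.125–2.625 wt%, so its first-layer weights
are numerically large and weight-path attribution inflates it, while the
liquid-lipid factor (range 0–60) carries small weights. Permutation
importance accounts for input variance and is the method to trust for
"which factor matters"; the two agree on scale-balanced (coded-space)
networks, which the tests assert on a separable example. For the same
reason the package makes no claim of reproducing any particular printed
importance percentages.

## Desirability optimization

Each response is mapped to [0, 1] by a linear (shape s = 1)
Derringer–Suich desirability — minimize particle size, PDI and zeta
potential, maximize %EE — and combined by the geometric mean, which has
the veto property (any zero component zeroes the whole). Anchors default
to the observed minimum and maximum of each response in the dataset, all
responses equally weighted; these choices are the package's own, since
only the goals (minimize/maximize) are given in the study design. The
reported 85.77% desirability value is therefore treated as qualitative.
"Minimize" is ambiguous for a signed zeta potential; the default is
literal (`raw`) minimization toward the most negative value, with
`zeta_mode = "magnitude"` minimizing |ζ| instead — provided because the
reported optimum's mid-range −10.85 mV suggests a compromise reading.

The search is deterministic: a regular grid over the coded [−2, 2]^4 box
followed by Nelder–Mead refinement from the best grid point, with points
outside the box scored zero and the final answer never allowed to fall
below the best grid value. The default grid step is 0.25 per axis
(17^4 = 83,521 candidates, evaluated as one vectorized forward pass,
well under a second); a finer step is a single argument away but offers
no practical benefit given the simplex refinement, since the composite
desirability surface is piecewise-smooth between anchor crossings. The
box itself comes from the factor table (`coded_min`, `coded_max`), so
narrowing the search region is a data edit, not a code change; no
extrapolation beyond the data-supported region is attempted.

## Release kinetics

Five classical release laws are fitted on the untransformed
%-released scale: zero-order Q = k·t, first-order Q = Q∞(1 − e^(−kt)),
Higuchi Q = k·√t, Hixson–Crowell (1 − Q/Q∞)^(1/3) = 1 − k·t, and
Korsmeyer–Peppas Q/100 = k·t^n. Zero-order and Higuchi are linear
through the origin and solved in closed form; the rest use
Levenberg–Marquardt started from the linearized fit. Q∞ defaults to 100%
(complete release) and is configurable for the two saturation laws. R²
is always computed on the Q scale so models are comparable. The
Korsmeyer–Peppas fit uses all points by default, with an optional
conventional Q ≤ 60% cutoff.

Ranking is by small-sample-corrected AIC (AICc), not raw R². The reason
is structural: Korsmeyer–Peppas nests both Higuchi (n = 0.5) and
zero-order (n = 1), so on noisy data its raw R² is never lower than
theirs and an R²-ranked table would select the power law on every noisy
diffusion-controlled profile — including profiles generated *by* the
Higuchi law. AICc admits the extra exponent only when it buys a
substantial residual reduction; in the package's simulations
(Higuchi-generated profiles, 2% noise, 6–12 sampling times) the
generating model is ranked first in ≥ 95 of 100 seeds. Two numerical
guards: the SSE entering AICc is floored at 1e-9·SST so exact fits of
noiseless data are compared by parsimony rather than floating-point
residue, and the small-sample correction denominator n − k − 1 is capped
below at 0.5 so three-point profiles (where the correction is undefined)
still rank; the cap affects all one-parameter models equally and so
never changes their relative order.

## Assay metrics

Entrapment efficiency is %EE = 100·(C₁ − C₂)/C₁ from the total (C₁) and
free (C₂) marker concentrations; it is unit-invariant and rejects
C₂ > C₁ as an assay inconsistency. The HET-CAM irritation score is
5·(301 − t_H)/300 + 7·(301 − t_L)/300 + 9·(301 − t_C)/300 over the onset
times (s) of hemorrhage, lysis and coagulation within a 300 s window. An
endpoint that never occurs contributes zero — the convention is not
stated anywhere authoritative, but it is the only reading that gives the
saline negative control its reported 0.00 score. Onset times outside
[1, 300] s are rejected, not clipped. The published category scale
(nonirritant to strong) leaves gaps between its printed bin edges
(0.9→1, 4.9→5, 8.9→9); classification uses half-open bins [0,1), [1,5),
[5,9), [9,∞) so every score classifies, which reproduces all the
reported category calls.

## Synthetic data: what it emulates, what it does not

`simulate_dataset()` draws replicate observations around a truth
network's predictions at the design points — by default the published
network with per-response Gaussian noise whose SD is the median of the
packaged dataset's per-run replicate SDs (computed at call time, roughly
2.3 nm, 0.025, 1.7 mV, 3.5%), three replicates per run, means clipped to
the physical ranges of PDI and %EE with a warning. A heteroscedastic
mode scales noise with the predicted mean. `simulate_release()` and
`simulate_hetcam()` generate release curves from any of the five kinetic
laws and per-egg onset-time tables whose expected scores fall inside a
target category. All generators are pure functions of their arguments
and seed.

The generator emulates replicate noise around a smooth truth surface. It
does not emulate run-order drift, batch effects, heteroscedasticity
beyond the optional mean-scaling, non-Gaussian outliers, or measurement
floors — so passing recovery tests demonstrate correctness of the
estimation machinery under the stated noise model, not robustness of the
laboratory workflow.

One negative result from this machinery is worth stating plainly,
because the test suite computes it: with the published network as truth
and study-scale noise, a freshly trained 4-9-9-4 network does *not*
reach held-out R² ≥ 0.8 per response on random 24/6 splits (the suite's
recovery check measures medians near or below zero for several
responses, and the corresponding test fails honestly). The surfaces the
published coefficients encode contain sharp tanh saturation ridges, and
24 CCRD support points do not pin them down once a fold including axial
or corner points is held out; a quadratic response-surface baseline
fails the same check. Training-set fit, by contrast, is easily
reproduced (R² ≥ 0.9731 for particle size, asserted at the reported
value). The practical reading: this design supports interpolation and
optimization inside the box far better than it supports out-of-sample
validation of so flexible a surrogate, and near-perfect held-out
statistics for such models should be read with care.

## Problem sizes and runtime

The test suite trains networks with 2–20 restarts at 150–500 BFGS
iterations (a single restart takes well under a second at this size),
runs the 10-seed recovery study, the 100-seed kinetics ranking study and
a 40-seed HET-CAM sampler check; the whole suite completes in well under
a minute on one CPU. The acceptance script trains once with 20 restarts
and evaluates the published network; it finishes in a few seconds.

## Known limitations

- The trainer targets small tabular designs; there is no minibatching,
  GPU path, or regularization beyond what restarts and the iteration cap
  provide.
- Weight-based importance is input-scale-dependent (see above); report
  it alongside permutation importance, never alone.
- Desirability anchors default to observed response ranges; predictions
  can leave those ranges inside the box (the surrogate is nonlinear), in
  which case the desirability saturates at 0 or 1 by design.
- The kinetic candidate set is the five classical laws; Weibull,
  Baker–Lonsdale and mechanistic diffusion models are out of scope.
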