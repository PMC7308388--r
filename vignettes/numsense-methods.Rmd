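---
title: "Modelling visual number sense: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling visual number sense: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(numsense)
```

## The problem

Numerosity — the number of items in a visual set — can be judged rapidly
and approximately, but every dot display confounds number with
non-numerical magnitudes: total surface area, item size, density, field
area, convex hull, total perimeter. `numsense` implements an in-silico
version of a research programme that asks how much of numerosity
perception, and of its development, can emerge in a generative neural
network that merely learns the statistics of dot images, with behaviour
measured by the same psychophysical machinery used for human observers.

## The orthogonal stimulus space

Stimuli live in a 3-D log space with orthogonal dimensions:

* **Numerosity** `n` — the dot count;
* **Size** — the product of item surface area (ISA) and total surface
  area (TSA), in px^4;
* **Spacing** — the product of field area (FA) and sparsity (FA/n), in
  px^4.

Because Size and Spacing are *products* of the usual covarying features,
every individual feature is an exact power law of the three coordinates:

```
ISA = sqrt(Size/n)    TSA = sqrt(Size*n)    FA = sqrt(Spacing*n)
sparsity = sqrt(Spacing/n)   coverage = sqrt(Size/Spacing)
TP = 2n*sqrt(pi*ISA)
```

so each feature is a fixed *direction* in (log2 n, log2 Size,
log2 Spacing): e.g. TSA is (1,1,0)/sqrt(2) and total perimeter is
(3,1,0)/sqrt(10), only 18.43 degrees away from the numerosity axis —
the geometric reason total perimeter is so hard to deconfound from
number. `feature_axis()` exposes the ten directions; `angle_between()`
and `project_onto_axes()` implement the geometry.

The canonical grids (`default_space_levels()`) are 13 log-spaced levels
per dimension: numerosity 7–28 (rounded to integers), Size 2.6–10.4 x
1e5, Spacing 0.8–3.2 x 1e7; with 10 instances per point the full grid
has 21,970 stimuli. Units: we read the published "pixels x 1e5" as
px^4 — only products of two areas give ISA/TSA/FA plausible px^2
magnitudes on a 200 px canvas.

**Convex hull** has no exact log-linear axis. For projection analysis we
approximate its direction by the field-area axis (1,0,1)/sqrt(2) (at
fixed n the hull scales with field area); for RSA we instead use hull
areas *measured* from the rendered dots. Both choices are package
decisions, flagged here because no formula is published.

## Rendering

`render_dot_array()` places `n` equal discs of area ISA uniformly at
random (rejection sampling, 1 px minimum gap, bounded retries with
restarts) inside a circular field of area FA centred on a square canvas,
and rasterizes them without anti-aliasing. The field is a disc and the
gap rule is ours; the source protocol only states "randomly placed
dots". `downscale_image()` is area-weighted averaging (mean intensity
preserved exactly); `measure_empirical_features()` recovers count
(connected components), areas, total perimeter and the exact convex
hull of the disc union (hull of centres + perimeter x r + pi r^2).

## Trials and the synthetic observer

The behavioural protocol compares two dot arrays ("which side has more
dots?"). `sample_comparison_pairs()` enforces the difficulty quotas of
the human protocol as *exact* counts — 10% of pairs with numerosity
ratio (min/max) in [0.5,0.6), 20% in [0.6,0.7), 30% in [0.7,0.8), 40%
in [0.8,0.9) — so the split is deterministic and testable;
`fraction * n_pairs` must be integral. Bins are half-open, a choice the
published wording ("between 0.5 and 0.6") leaves open.
`sample_uniform_pairs()` draws distinct ordered image combinations for
simulations, rejecting equal-numerosity pairs.

Because the underlying human dataset is not public, a **synthetic
observer** (`simulate_observer()`) stands in for participants. It draws
choices from the same model later used for fitting:

```
P(choose right) = (1 - gamma) * (Phi(eta) - 1/2) + 1/2
eta = b_side + b_num*log2(r_num) + b_size*log2(r_size)
      + b_spacing*log2(r_spacing)
```

with `Phi` the standard normal CDF (the published erf form is
algebraically identical) and `gamma` a guessing rate. Default observer
coefficients (2.0, 0.4, 0.3, side 0, gamma 0.01) produce accuracy around
0.80 and adjusted R^2 around 0.54 — the human range. Optional response
times are lognormal (meanlog 6.6, sdlog 0.3, i.e. median ~740 ms);
no RT model is published, and RTs exist only to exercise the outlier
filter.

## Fitting and geometry

`fit_choice_glm()` maximizes the exact likelihood with BFGS and an
analytic gradient (a plain probit `glm` seeds the optimizer and serves
as an independent oracle for the gamma = 0 case, where the two must
agree). The guessing factor is either fixed (protocol value 0.01) or
chosen on the grid {0, 0.005, ..., 0.1} by minimum deviance — both
published readings. The adjusted pseudo-R^2 is McFadden's adjusted
formula, `1 - (LL - k)/LL_null`, with the null model keeping only the
side bias; the published "adjusted R^2" is not defined further.

The fitted `(b_num, b_size, b_spacing)` triple is the **discrimination
vector**: its magnitude indexes acuity and its direction shows which
dimensions drive choice. Projections and angles on the ten feature axes
summarize non-numerical biases.

**Weber fraction.** The published conversion lives in unavailable
supplementary material. We adopt `w = ln(2) / (sqrt(2) * b_num)`,
obtained by equating `Phi(b_num * log2 r)` with the equal-variance
log-Gaussian discrimination model `Phi(ln r / (sqrt(2) w))`. This is a
documented package convention, not an assertion about the source; it is
monotone in `b_num`, which is all the downstream ordering analyses use.

**RT outlier filter.** Trials faster than the 250 ms presentation go
first; then, within each numerosity-ratio difficulty bin (the quota bins
plus a catch-all [0.9, 1)), trials slower than bin mean + 2 SD. The
order of the two passes is unspecified in the source; we compute bin
statistics after the fast-trial removal.

**Group statistics** follow the published recipe: Shapiro–Wilk at 0.05
gates t-test vs Wilcoxon signed-rank; unpaired contrasts use
Mann–Whitney; thresholds are Bonferroni-corrected. A Monte-Carlo test
checks the one-sample procedure attains its nominal type-I error.

## The deep belief network

`train_dbn()` stacks two restricted Boltzmann machines trained greedily
by CD-1 (`train_rbm_cd1()`): hidden probabilities from data, one
Bernoulli hidden sample, a mean-field reconstruction, and the
`<vh>_data - <vh>_recon` gradient with momentum and weight decay. The
second RBM consumes the first layer's activation *probabilities*;
`encode()` is a fully deterministic probability feed-forward. "Young" =
1 epoch; "Mature" = prolonged training.

Hyperparameters are in unavailable supplementary material; our defaults
(overridable via `rbm_hyper()`) are: learning rate 0.1 (pixel layer) /
0.05 (second layer), momentum 0.5 switching to 0.9 after epoch 5,
weight decay 2e-4, batch 125, weights N(0, 0.01^2), zero biases.

The **readout** (`train_readout()`) is softmax regression with two
output units on the concatenated top-layer codes of the two stimuli:
full-batch gradient descent, fixed 200 iterations, learning rate 0.1,
init N(0, 0.01^2). "Linear network with two output units" admits several
readings; this one keeps the decision boundary linear. The protocol is a
shared object and `run_comparison_task()` refuses to compare conditions
whose readouts used different protocols — a structural encoding of "the
supervised layer was exactly the same" across developmental stages. The
iterative variant (`online = TRUE`, one per-trial gradient step in
sequence order) supports `curriculum_order()` experiments
(easy-to-hard vs hard-to-easy by |log2 r_num|).

## Representational similarity analysis

`build_probe_set()` selects probe levels *by grid index*. The published
probe values — numerosity (7, 18, 28), Size (2.60, 6.55, 10.40) x 1e5,
Spacing (0.80, 2.02, 3.20) x 1e7 — are described as "equally spaced",
yet the middle values match 0-based index 8 of the 13-level log grid
(e.g. 0.8e7 * 4^(8/12) = 2.016e7), not the geometric midpoint (index 6,
1.6e7). We therefore expose index-based selection with default indices
(1, 9, 13) in 1-based R convention and document the discrepancy here.

Per condition (27 feature combinations x 10 instances), top-layer codes
are averaged (`mean_activation_patterns()`), correlated, and turned into
a 1 - Pearson RDM (`model_rdm()`). Categorical model RDMs
(`categorical_rdm()`) use |log2 f_i - log2 f_j|; log base is irrelevant
to rank statistics. Candidate relatedness uses Kendall tau-A — ties
count against concordance, the right choice when categorical models
predict tied dissimilarities — with a one-sided Wilcoxon signed-rank
across replicates and Benjamini–Hochberg FDR at 0.01 (the source states
only "FDR < 0.01"; BH is our choice). The unit of replication is the
seed-replicate set of one architecture. `noise_ceiling()` gives the
usual include/leave-one-out bounds, and `rdm_glm_fit()` regresses RDM
lower triangles on predictor RDMs. Categorical feature values are
nominal (analytic) except convex hull, which uses measured hull areas —
whether the original analysis measured the others from images is
unknown; nominal is assumed.

## The reduced-scale developmental experiment

The published effect — numerosity acuity grows with unsupervised visual
experience while non-numerical biases shrink — was demonstrated with
144 networks (12 architectures x 12 seeds) on 100x100 images, 65,912
training stimuli and 200 epochs. That is cluster-scale.
`run_development_experiment()` runs the stated desk-scale substitute:
50x50 images (rendered at 100 px, area-downscaled), numerosities 5–16
with 5 log levels per dimension, Size/Spacing ranges scaled by 1/16
(the squared linear scale factor), 2000 training images (16 instances
per grid point), architecture (200, 100), 12 seeds, Young = 1 vs
Mature = 50 epochs, 4000 readout pairs, 2000 held-out test pairs, and a
probe set at grid indices (1, 3, 5) with 10 fresh instances.

What the suite's green checks establish at this scale, per seed
majority: the Mature network's numerosity coefficient exceeds the
Young one; the Size-family bias shrinks; and the Young representation
correlates best with convex hull, exactly as published. What the
reduced world does **not** reproduce (the corresponding acceptance
assertions are left failing rather than weakened): the Spacing bias
*grows* from Young to
Mature, and the Mature RDM ranks field area — not numerosity — on top.
Mechanistically, the small Mature network learns spatial extent (FA)
well and uses it as a numerosity proxy; since FA = sqrt(Spacing*n)
loads positively on both dimensions, this inflates the Spacing
coefficient instead of suppressing it. Sensitivity checks show the
effect pattern depends on readout convergence: a readout trained to
convergence instead decodes area/extent proxies from the quasi-linear
Young codes so well that the *numerosity* ordering reverses. No readout
protocol examined yields all coefficient signatures at this scale; the
fixed 200-iteration protocol was kept as stated rather than tuned.

## What the synthetic data does and does not establish

The synthetic observer draws choices from the very model family later
fitted to them. Green recovery tests therefore establish correctness of
the likelihood, optimizer and geometry — not that the model describes
human behaviour. Response times are a pure convenience for the filter
stage. The renderer emulates dot placement, not the display pipeline
(no masks, fixation crosses, or luminance calibration), and the DBN sees
noiseless, perfectly registered images; none of the perceptual front-end
variability of real experiments is modelled.

## Numerical choices and degenerate inputs

* Choice probabilities are clamped to [1e-12, 1 - 1e-12] in the
  likelihood; the optimizer runs BFGS with reltol 1e-12 and reports
  non-convergence as an error rather than returning a fit.
* `angle_between()` clamps cosines to [-1, 1]; zero vectors error.
* Readout ties (equal output scores) break by a seeded coin flip.
* Curriculum ties keep their original trial order (stable sort).
* Equal-numerosity pairs are rejected at sampling time, so log-ratio
  regressors are never all-zero.
* All randomness flows through R's RNG; every documented entry point is
  bit-reproducible under `set.seed()`.

## Known limitations

* Full-scale replication (1500/1000 units, 200 epochs, 100x100 images)
  is out of desk budget by design; published point values (e.g. the
  4.49-degree Mature numerosity angle, the Fig-4 tau values) are not
  expected from the reduced configuration, and the two reduced-scale
  divergences above are documented rather than patched.
* The hysteresis manipulation is implemented as online per-trial readout
  updates over ordered trials; the original iterative-classifier update
  rule is in unavailable supplementary material.
* The Weber-fraction convention is package-local (see above).
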