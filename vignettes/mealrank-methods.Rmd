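---
title: "Ranking meal healthiness from images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking meal healthiness from images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealrank)
```

## The problem

Dietary-support systems want to tell a user, from a single photograph of a
meal, whether that meal is a healthy choice — without food-category
recognition, portion estimation, or manual input. mealrank implements a
learning-to-rank approach to this problem: a registered dietitian (here, a
simulated annotator) ranks meal images by overall healthiness; a Siamese
convolutional network learns a scalar score `f(x)` whose ordering reproduces
those ranks; the score is standardized into an interpretable 0–100
*deviation score*; and meals scoring below a threshold are flagged for
dietitian intervention.

Real patient meal photographs cannot ship with a package. mealrank therefore
contains a first-class synthetic world with a *known* latent healthiness, so
that every stage — annotation, training, scoring, screening, evaluation —
can be verified against ground truth.

## The synthetic world

A scene is 1–4 non-overlapping dish discs on a textured background
(64 × 64 RGB by default). Each dish has a composition over three visual food
classes — vegetable (green), fried (yellow–brown), staple (pale) — rendered
as concentric bands with band areas proportional to the fractions, so the
composition is recoverable from pixels and the vision task is solvable. The
mask is exactly the union of dish discs; per-pixel class labels support
segmentation pretraining.

Ground-truth healthiness is

\[ h = 2.0\,V - 1.5\,F + 0.5\,(D - 1), \]

with `V` and `F` the area-weighted vegetable and fried fractions and `D` the
dish count. The coefficients (configurable as `latent_coefs`) were chosen
once so that composition dominates dish count; the monotone directions
(vegetables up, fried food down, more dishes up) mirror the visual cues
practitioners associate with image-judged healthiness. Dish counts 1–4,
radii 7–11 px and flat Dirichlet compositions are stated modeling
assumptions, not facts about any real meal-photo distribution: nothing is
known publicly about the dish-count or plate-style distribution of the
patient databases such systems are trained on.

The simulated annotator perceives each latent through additive Gaussian
noise (`noise_sd`) and cannot distinguish values closer than
`tie_tolerance`; ties share a competition rank. Noise is drawn once per item
per session, so one session is internally consistent. With 1 000 repeated
two-item sessions, the preference probability matches the Gaussian
comparison model `pnorm(dh / (noise_sd * sqrt(2)))`, which the test suite
checks by Monte Carlo.

With `background_mode = "confounded"` the background hue is a deterministic
function of the latent (red behind unhealthy meals, green behind healthy):
this reproduces the situation food-region masking is designed to defeat,
where image context correlates with the label. `shuffle_backgrounds()`
re-renders the same dishes on fresh random backgrounds, breaking the cue at
evaluation time.

## Ranking sessions

Annotation uses screens of `n_c = 4` images: one pivot plus up to three
unplaced candidates. The returned ordering partitions candidates into
better-than / tied-with / worse-than the pivot; the two strict partitions
are ranked recursively (quicksort); items tied with a pivot adopt its rank
band. When the remaining set fits a single screen, that screen's full
ordering is adopted directly. The exact published algorithm behind this
protocol is not available; the procedure here is a reconstruction from the
stated screen structure, and is validated against a plain comparison sort:
for any set of distinctly-valued items and a noiseless annotator, the
session ranking equals the sorted ranking (property-tested to n = 64).

Pivots are uniform choices driven by a hash of (seed, item subset), so the
recursion tree for a given seed does not depend on `n_c`; with that fixed,
4-image screens provably never use more screens than pairwise (`n_c = 2`)
comparison on the same input.

Multiple annotators' sessions are merged with TrueSkill: each session is
decomposed into its strict pairwise outcomes and each outcome updates the
two items' Gaussian skill beliefs with the standard two-player
moment-matching equations (defaults mu0 = 25, sigma0 = 25/3, beta =
sigma0/2, tau = sigma0/100). Several deterministic sweeps are run so late
outcomes inform early beliefs; ties are treated as annotation shortcuts and
skipped rather than modeled as draws. The merged ranking sorts by posterior
mean.

## The ranking network

The scorer is a compact CNN: two 3 × 3 stride-2 convolution blocks (12 and
24 channels, ReLU) produce a per-pixel feature map at quarter resolution;
global average pooling and two fully connected layers (32 hidden units)
yield the scalar `f(x)`. Pooling before the head makes the score independent
of food location. The same network is implemented once and evaluated on both
members of a training pair (weight sharing); the pair loss is the logistic
(RankNet) form

\[ L(m) = \log(1 + e^{-m}), \qquad m = f(x_i) - f(x_j), \]

with pair orientation fixed so item *i* is the ground-truth healthier one.
`L(0) = log 2`, `L` is strictly decreasing, vanishes for confidently correct
orderings and grows linearly for confidently wrong ones, and satisfies
`L(m) − L(−m) = −m`. A hinge variant is available (`loss = "hinge"`) for
sensitivity checks. Training is Adam (default rate 2e-3) on minibatches of
16 pairs; all randomness (init, shuffling) derives from explicit seeds, and
training is single-threaded and bit-reproducible. Ties never produce
training pairs; whether down-weighting tied annotations would be preferable
is unknowable from the available description, so exclusion was chosen as
the conservative option.

**Masking.** Training inputs are multiplied pixel-by-pixel with the binary
food mask, so everything outside the food region is exactly 0 and the
network cannot learn background–healthiness associations. Input-level
multiplication is the primary mechanism; masked average pooling of the
feature map is available as `mask_pool = TRUE`. Masks are applied per meal
(union of dishes), not per dish.

**Segmentation pretraining.** The extractor plus a temporary 1 × 1
per-pixel head is first trained with class-weighted cross-entropy to label
each feature-map pixel as background / vegetable / fried / staple (labels
nearest-neighbour downsampled to the feature grid). Class weighting
(inverse frequency) matters: backgrounds are ~85 % of pixels and unweighted
training collapses to the majority class at this scale. The head is then
discarded and ranking training proceeds end to end from the pretrained
convolutional weights. Held-out per-pixel accuracy exceeds 0.95 within
twenty epochs on the synthetic classes.

**Evaluation protocol for masked models.** The network never *requires* a
mask at inference. However, at this deliberately reduced scale the
extractor is two convolution blocks, and a head trained exclusively on
zeroed backgrounds does not transfer to textured backgrounds it has never
seen: in our experiments held-out Spearman drops from ≈0.97 to ≈0.2 when a
mask-trained model scores raw images. A full-scale segmentation backbone
pretrained on a large food dataset — the component this package deliberately
replaces with a small surrogate — is what makes mask-free inference viable.
The package therefore adopts the protocol that mask-trained models are
*evaluated* on the food region (the screening database carries a mask for
every image, so this is always available), while mask-off models are
evaluated on raw images; `score_meals()` defaults accordingly and
`score_image()` stays mask-free. Conclusions about masking in the ablation
grid compare each condition under its own deployment convention.

## Scores and screening

Raw outputs have no absolute meaning, so they are reported as deviations
from a reference population: `z` is the raw score standardized against the
reference mean and *population* SD (the reference is the population of
interest, not a sample from something larger), and the user-facing score is
the deviation-score convention

\[ s = 50 + 10 z, \]

clipped to [0, 100]. Self-referenced scores therefore have pre-clip mean
exactly 50 and SD exactly 10. Min–max scaling to 0–100 is available as
`score_transform = "minmax"`; which exact transform the original system used
is not documented, and the deviation convention is the one consistent with
"distance from the mean normalized by the variance". Screening flags
`s < Th`; `threshold_for_quantile()` picks `Th` as the k-th percentile
(quantile type 7, linear interpolation — bit-reproducible) of a reference
score set, so screening flags at most the worst k % of the reference
(strict inequality).

## Evaluation suite

* `pairwise_error()` — E_p: over unordered pairs with strictly different
  reference scores, the fraction whose estimated order disagrees.
  Reference-tied pairs are excluded from the denominator; estimated ties
  count as errors (the source description is silent on ties; this is the
  conservative reading and is pinned by tests).
* `order_error()` — E_o: mean absolute difference between an item's
  positions in the estimated and reference orderings; ties in either score
  vector are broken deterministically by item id. On tie-free data the
  tie-break cannot matter (tested).
* `rank_correlations()` — both the Pearson correlation of normalized order
  vectors and Spearman on raw scores, since "the correlation of rankings"
  is ambiguous between the two.
* `bland_altman()` — bias, 1.96-SD limits of agreement, and the
  proportional-bias slope (differences regressed on pair means).
* `detection_eval()` — unhealthy-meal detection: an item is unhealthy when
  its reference rank falls in the lower k % (k ∈ {50, 60, 70} are the
  conventional choices); ROC is swept over midpoints between consecutive
  distinct scores plus infinities, AUC is trapezoidal. The staircase is
  cross-checked against an independent ROC implementation (pROC) in the
  tests.
* `ranksvm_baseline()` — a linear scorer on frozen pooled extractor
  features, fit on pairwise feature differences with an L2-regularized
  squared-hinge objective from w = 0 (deterministic). C defaults to 1.
* `run_ablation_grid()` — masking × pretraining × {CNN, Rank-SVM} with a
  shared split and shared seeds per repetition.

## Benchmark problem sizes

The package's reference benchmarks, chosen once as desk-scale stand-ins for
a several-hundred-image annotation study:

* *Rank recovery*: 300 items, noiseless annotator, 90/10 item split
  (the conventional train share), ≤2 000 training pairs, 15 epochs.
  Typical results: held-out Spearman ≈ 0.97, pairwise accuracy ≈ 0.93.
* *Ablation grid*: 120 items with confounded backgrounds, evaluation on
  background-shuffled test images, 250 training pairs, 12 epochs, 3
  repetition seeds. The small pair budget reflects the data-poor regime in
  which pretraining earns its keep.
* The pipeline smoke benchmark uses 16–32 px images and a few epochs purely
  to exercise the plumbing.

## What passing tests do and do not show

The synthetic world is color-coded and noise-free by default: composition
is linearly decodable from pixels, backgrounds are statistically simple,
and the latent function is exactly the quantity the annotator ranks.
Passing benchmarks therefore demonstrate the *correctness of the
machinery* — data generation, session logic, pair learning, score
normalization, screening and metrics — not transfer to photographs of real
meals. Real images bring texture, lighting, occlusion, unmodeled dish
types and annotator idiosyncrasies that this package intentionally leaves
out of scope.

## Numerical and degenerate-input conventions

* All generation, annotation, training and evaluation are pure functions of
  `(config, seed)`; per-stage seeds derive from one global seed and the
  stage name.
* Zero-variance references, singleton references, all-tied rankings and
  single-class detection labels raise structured errors (or a warning plus
  a defined partial result, for single-class ROC).
* The logistic loss is computed as `max(−m, 0) + log1p(exp(−|m|))`, exact
  and overflow-free for any representable margin.
* CSV artifacts are written with 17 significant digits so doubles
  round-trip bit-exactly; every artifact embeds the config hash, and
  loaders refuse mixed-config combinations.

## Known limitations

* No GPU path and no minibatch parallelism; the implementation favors exact
  reproducibility over speed.
* The extractor is far smaller than a modern segmentation backbone; its
  features are sufficient for the synthetic classes but would not transfer
  to photographs.
* Rank-SVM is fit on pooled (image-level) features; the original
  formulation on pixel-level features would be substantially more
  expensive.
* TrueSkill sweeps use a fixed deterministic schedule rather than full
  factor-graph message passing; for consistent sessions this converges to
  the same ordering, which is the property the tests pin.
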