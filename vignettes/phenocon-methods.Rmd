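---
title: "Semisupervised contrastive representations of morphological profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semisupervised contrastive representations of morphological profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenocon)
```

## The problem

High-content screens image cells treated with thousands of compounds across
several fluorescence channels (Cell Painting). Only a fraction of the
compounds carry bioactivity annotations — pharmacological classes such as
MeSH categories, modes of action, or targets — and a central task is to place
*all* treatments, annotated or not, into a phenotypic space where proximity
reflects shared bioactivity. phenocon learns that space with semisupervised
contrastive learning and then uses it three ways: cross-validated bioactivity
classification, per-class reliability deconvolution, and loss-based
prioritization of unannotated compounds for de novo annotation.

## The representation model

An encoder `f` (a convolutional network) and a projector head `g` (a small
MLP) map an image `x` to a latent `z = g(f(x))`, which is L2-normalized so
that temperature-scaled dot products are cosine similarities. Normalization
is a design choice of this package: it is what makes the contrastive
objective scale-free, and the reference loss implementations in this
literature do the same.

Training operates on *multiviewed batches*: N anchor images are sampled and
each is paired with a randomly chosen replicate of the same compound
treatment, giving 2N entries. Replicates — images of the same treatment
acquired in different wells and plates — play the role that synthetic
augmentations play in standard contrastive learning, so the representation
is pushed to be invariant to plate/batch effects rather than to crops or
color jitter.

With `i` an anchor, `j(i)` its replicate and `A(i)` the other `2N - 1`
entries, the self-supervised loss is

$$
L^{self} = \frac{1}{2N}\sum_i
  -\log\frac{\exp(z_i \cdot z_{j(i)}/\tau)}
            {\sum_{a \in A(i)} \exp(z_i \cdot z_a/\tau)} .
$$

On the annotated subset, every entry sharing the anchor's class belongs to
the positive set `P(i)` (the replicate always does, since paired entries
share their compound's label), and the supervised loss averages the
log-ratio over positives *outside* the logarithm:

$$
L^{sup} = \frac{1}{2N}\sum_i \frac{-1}{|P(i)|}\sum_{p \in P(i)}
  \log\frac{\exp(z_i \cdot z_p/\tau)}
           {\sum_{a \in A(i)} \exp(z_i \cdot z_a/\tau)} .
$$

The sum-outside-log variant is implemented deliberately; an inside-log
variant exists in the literature and is *not* equivalent. When every
positive set is the singleton replicate, `L_sup` reduces exactly to
`L_self` — a property the test suite asserts. Both losses use
max-subtracted log-sum-exp; both are non-negative; `L_self` is 0 for a
single pair and `log(2N - 1)` for coincident latents.

Each training epoch runs two phases: phase A steps on `L_self` over batches
covering the entire image set (controls included); phase B steps on
`supervised_weight × L_sup` over batches drawn only from images of
annotated compounds, labeled with each compound's *first* annotation.
Annotations act purely through the positive sets — no classifier is fit
during representation learning. Training is transductive by design: the
annotated test-fold compounds participate in phase B, because the goal is a
good representation of *this* screen's treatments, not generalization to
unseen images. Whether the two phases should interleave at batch rather
than epoch granularity is genuinely open; epoch-level alternation was
chosen and fixed.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `temperature` | 0.07 | sharpness of the similarity softmax |
| `learning_rate` | 10^-2.5 | RMSprop step size (momentum-free adaptive optimizer, no scheduler) |
| `projector_dim` | 224 | width of `z` |
| `batch_size` | 40 | anchors per multiview batch (2N = 80 images) |
| `max_epochs` | 250 | upper bound on epochs |
| `supervised_weight` | 1.0 | gradient weight of phase B |

The encoder is a compact patch-convolution CNN: non-overlapping
patch convolutions (patch sizes 4, 2, 2; 16/32/64 filters) with ReLU,
global average pooling, and a two-layer projector. Patch convolutions with
stride equal to kernel size keep the hand-written backward pass an exact
reshape, and the whole network trains on a single CPU; all architecture
sizes are configurable. Gradients of both losses and of every layer are
verified against finite differences (relative error below 1e-4 in tests;
measured ~1e-7).

## Downstream analysis

`z` itself is the image representation. Downstream classifiers are
deliberately boring and identical across representations: a random forest
(500 trees, sqrt-mtry, seeded, single-threaded) for single-label
(first-annotation) prediction and one-vs-rest multilabel prediction, and a
3-layer MLP head (512 and 256 hidden units, ReLU, 50% dropout on the first
two layers, sigmoid outputs with binary cross-entropy, learning rate
10^-2.5, early stopping on a 10% validation slice with patience 10) for
multilabel prediction. Multilabel scores become label sets at a 0.5
threshold; this threshold is a package choice (the strict exact-match
accuracy depends on it heavily) and is exposed in the configuration.

Splits are *treatment-level*: 5-fold cross-validation assigns annotated
compounds (never images) to folds, so every image of a compound sits on one
side of every split — the no-leakage invariant is asserted on every run.
Folds are stratified by primary label when a class has at least as many
members as folds. Metrics are computed per image, without replicate
aggregation, except in the explicit replicate-vote readout
(`predict_compound_classes`).

Metrics: exact-match accuracy (a prediction is correct only if the entire
predicted label set equals the truth), macro-averaged PR AUC (average
precision per class from the full score ranking with step integration — no
linear interpolation, a convention that changes the value and is therefore
fixed and tested against a brute-force staircase), and per-class
precision/recall/F1 deconvolution. Deconvolution computes the metrics per
fold (percent; 0/0 ratios defined as 0) and averages *each metric* across
the folds in which the class appears. Averaging per-fold F1 is not the same
as taking the harmonic mean of averaged precision and recall; the report
deliberately does the former, and a class is flagged reliable when its
fold-mean precision reaches 10%.

## Ranking unannotated compounds

Each image is scored by its per-anchor self-supervised loss term inside
fixed, seeded multiview batches; a compound's score aggregates its
replicates' terms, by default the minimum (the most self-consistent
replicate), with the mean exposed as an alternative — the source analyses
are ambiguous between the two, so both are first-class. Low scores mark
treatments whose replicates land in a tight, distinctive region of latent
space; the lowest-scoring unannotated, non-control compounds are reported
with the top-3 classes most frequently predicted across their replicates by
the single-label random forest. Controls are excluded (a vehicle is not a
discovery candidate), as are annotated compounds — note that the supervised
phase actively merges annotated same-class compounds, which would confound
a replicate-consistency score. Batch composition affects the scores; it is
fixed by seed and recorded, and sensitivity to it is a documented caveat.

## The synthetic data generator

Real Cell Painting sets are far too large to ship or retrain at desk scale,
so the package carries a generator whose outputs exercise every module.
Its generative model, in full:

- **Classes.** Each of K latent classes holds per-channel parameters:
  oriented sinusoid frequency/phase/amplitude (texture) and Gaussian-blob
  rate/radius/amplitude (punctate structure).
- **Compounds.** Each compound inherits its class template with its own
  deviations (frequency ±12%, amplitude ±30%, phase sd 0.8, blob rate
  ±50%) plus a private low-amplitude fingerprint sinusoid. This
  compound-individuation level matters: it realizes the variance hierarchy
  of a real screen — replicates of one compound resemble each other more
  than same-class compounds do — without which same-class treatments are
  indistinguishable clones and both downstream evaluation and
  replicate-consistency ranking become degenerate.
- **Replicates.** Each replicate expresses the compound phenotype scaled by
  `signal_strength`, with inconsistency controlled by `replicate_noise`
  (scalar or per-compound): one unit mixes in up to 35% of a random
  contaminant class phenotype per replicate (an off-target/toxic response
  differing between replicates), jitters expressed strength by 15% sd, and
  adds pixel noise (sd 0.08) and 5% brightness jitter. Replicates spread
  round-robin over 2 synthetic plates, each plate applying a per-channel
  gain (sd 0.15 × `batch_effect`) and offset (sd 0.04 × `batch_effect`).
- **Controls.** DMSO-like images draw from the shared background process
  (constant level plus generic blobs) with no class component.
- **Annotation.** A class-stratified fraction of compounds receives its
  true class as first label; a fraction of those receives a second,
  correlated label (the cyclically next class). Everything is a
  deterministic function of the spec, and pixels are quantized to 16-bit
  levels so the TIFF round trip is exact.

What the generator does *not* emulate: real cell morphology, segmentation
artifacts, spatial plate-position effects, heavy-tailed intensity
distributions, or annotation noise. Passing tests therefore demonstrate
that the algorithms behave as specified on data with known structure — not
that the defaults reproduce any particular screen's numbers.

## Study sizes and numerical choices

The standard synthetic benchmark used by the tests and the acceptance
script is 10 classes, 80 compounds × 4 replicates, 48×48×3 images, 50%
annotated, a small CNN (projector width 32), 15 epochs, 3 seeds — sizes
chosen so the whole study runs in minutes on one CPU while leaving room
between the majority baseline (10%) and ceiling. On it, semisupervised
embeddings beat self-supervised-only embeddings by tens of accuracy points:
self-supervision alone clusters *compounds* but has no reason to organize
*classes*, which is exactly the gap annotations close. The ranking study
reuses the benchmark with `replicate_noise` cycling over {0, 0.5, 1, 1.5,
2} across compounds and checks that the aggregated batchwise loss orders
compounds by their inconsistency (Spearman 0.65–0.77 across the three
benchmark seeds) with zero-noise compounds dominating the top ranks. This
correlation is noticeably seed-variable in the small-data regime: with only
~340 training images the encoder can, on some runs, collapse even
inconsistent compounds' replicates (the correlation is not monotone in
training epochs), so individual runs below the benchmark values are
expected and the ranking should be read as a prioritization heuristic, not
a calibrated score.

Other fixed numerical choices: bilinear interpolation for resizing; an
explicit user-suppliable C×3 channel mixing matrix for RGB conversion
(default: channels partitioned over R/G/B with overlaps averaged, recorded
with the output) because the original preprocessing delegated this to an
external imaging tool whose exact mapping is unrecoverable; per-image
max-reference normalization at preprocessing (not load) time, toggleable;
unit-norm enforcement with tolerance 1e-3 at the loss boundary; a
degenerate image whose activations die completely maps to the first basis
vector with zero gradient; single-image compounds self-pair (the slot
pairing stays a fixed-point-free involution); count ties in replicate votes
and score ties in rankings break lexically.

## Known limitations

- The encoder family is the built-in compact CNN; no pretrained ResNet-scale
  backbone ships with the package, so absolute accuracies on real screens
  are not comparable to GPU-scale studies.
- Exact-match multilabel accuracy is threshold-sensitive; comparisons
  across thresholding rules are not meaningful.
- Batchwise loss scores depend on scoring-batch composition; only the
  seeded procedure is reproducible, not the score of an image in isolation.
- The supervised phase uses only each compound's first annotation;
  remaining labels influence evaluation but not representation learning.
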