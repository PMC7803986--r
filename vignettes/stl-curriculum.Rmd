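---
title: "Curriculum training for food segmentation: methods and design notes"
author: "stlseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum training for food segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Per-pixel classification of food items on canteen trays is hard where
classes are visually correlated: many dishes differ only in subtle color
and texture cues (pasta variants tossed in near-identical sauces, say), and
a network trained on all classes at once tends to split its prediction mass
between look-alike candidates. `stlseg` implements a curriculum remedy,
*sequential transfer learning* (STL): let the network first solve a coarse
version of its own problem, then re-pose the same data with progressively
finer labels, carrying all weights except the classifier head from round to
round.

The coarsening is not hand-designed. It is read off the network itself:
after a conventional pre-training pass, a prototype feature vector is
extracted per class from the encoder bottleneck, the prototypes are
clustered agglomeratively, and the resulting dendrogram is cut below its
greatest link heights. Each cut defines one training stage; classes merged
below the cut share a label at that stage.

## Data preparation

Training operates on single-class ROI patches, not whole trays. Every
annotated bounding box becomes one patch-mask pair; pixels inside the box
that belong to any other class are relabeled background (0), so a pair
shows exactly one food class. Boxes are half-open 0-based pixel rectangles
`[x0, x1) x [y0, y1)` — the manifest readers document this convention
because annotation formats in the wild disagree silently.

Variable-size crops are *resized* (bilinear for the image, nearest
neighbour for the mask with the half-pixel-center index rule
`src = floor((dst + 0.5) * n_in / n_out)`) rather than padded to the
training patch size. Padding would preserve aspect ratio but inject large
synthetic background areas into single-class patches; resizing keeps the
foreground fraction of each patch intact, which the hit-ratio metrics
depend on. Whether the original study resized or padded is not recoverable
from its text; this is the package's choice and it is applied uniformly.

Augmentation is the four-fold flip group (identity, horizontal, vertical,
both), applied identically to patch and mask: 2255 raw pairs become 9020.
The validation split draws `round(0.2 n)` pairs (half-up) after a shuffle
by a dedicated seeded generator, independent of the training seeds — 7216
training and 1804 validation pairs at full scale, giving 361 steps per
epoch at batch size 20. For evaluation, classes with fewer than a minimum
number of test patches (15 by default) are expanded by cycling round-robin
through the originals and drawing, per visit, the patch's next unused
transform in the fixed order rot90, rot180, rot270, vflip+rot90,
vflip+rot180, vflip+rot270, vflip — at most 7 new patches per original.
The round-robin order spreads the transforms as evenly as possible across
originals; the exact ordering within the seven is the package's own
convention.

## The network

The segmentation model is a U-Net-style encoder-decoder: `depth` encoder
blocks of two same-padded 3x3 ReLU convolutions each, followed by 2x2 max
pooling; a two-convolution bottleneck; a mirrored decoder whose blocks
upsample (nearest neighbour), halve the channels with a 2x2
"up-convolution", concatenate the skip connection and apply two more 3x3
convolutions; and a 1x1 convolution head with `C` output channels under a
per-pixel softmax. Filter counts double per encoder level and halve per
decoder level, so the layer count is `5 * depth + 3` convolutions — 28 at
the published configuration (input 256x256, base 32, depth 5, bottleneck
1024 channels). Same-padding is used throughout instead of the original
U-Net's crop-and-copy so predictions keep the input size.

Forward and backward passes are implemented in the package (im2col
convolution kernels in compiled code, exact analytic gradients — verified
against central finite differences in the test suite), with Adam at its
cited defaults (learning rate 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8).

Two initialization choices deserve a note:

* *No zero initialization.* Initializing every weight to zero — as the
  procedure is sometimes described — leaves a network whose hidden units
  receive identical gradients and never diverge; the reported training
  behavior is only reachable with a symmetry-breaking initialization.
  Hidden convolutions therefore use seeded He-normal draws
  (`sd = sqrt(2 / fan_in)`), bit-reproducible given the configuration
  seed.
* *Small head initialization.* The 1x1 classifier head uses a small
  variance (`sd = 0.01`) instead. A freshly swapped head then emits
  near-zero logits — near-uniform predictions, initial loss `log C` — so
  the first gradient steps adapt the head to the carried-over features
  rather than flooding those features with large noisy gradients. This
  preserves the transfer the curriculum relies on, and is the one place
  where a near-zero initialization is both trainable and useful.

`replaceHead()` swaps only the head; every other parameter is carried over
and bit-identical before and after — the invariant the whole method rests
on, asserted exactly (sum of absolute differences equal to zero) in the
tests.

## Class prototypes and clustering

After conventional pre-training, `k = 3` patches are sampled per class
(without replacement where possible) and each patch's bottleneck volume
(`H/2^depth x W/2^depth x D`) is collapsed to a length-`D` vector by
per-channel spatial averaging; class rows are the mean over the `k`
vectors. Spatial averaging resolves a tension in the source description —
a depth-wise "serialization" is described, yet a 1024-variable observation
matrix is analyzed; global average pooling is the reduction that yields
exactly `D` variables. The raw serialization remains available behind the
`feature_origin` tag for comparison, as does a training-free
color-statistic route (foreground mean and standard deviation per channel)
used by the synthetic experiments.

For wide backbone features (the reference case: 32x32x4096 volumes, 4.19
million values when serialized), `reduceDeepVolume()` rearranges the
volume depth-wise into an `(H'W') x D` matrix — row-major spatial order, a
convention the package documents because the source is silent — fits PCA
on that per-volume matrix, keeps 50 components, and serializes the score
matrix row-major into a 51,200-vector.

Prototype rows may optionally be projected onto principal components
before clustering (default: applied when there are more features than
classes, retaining 95% variance); whether the original analysis clustered
scores or raw features is ambiguous, so both paths are exposed.

Clustering is agglomerative via `stats::hclust`. Linkage is configurable
(single, complete, average, Ward); the default is Ward on Euclidean
distances, which produces the balanced, compact groups a curriculum wants
— a singleton absorbed at the last merge (typical of single linkage) makes
a useless stage. Cuts are taken infinitesimally below the `k` greatest
*distinct* link heights, ties severed together; that is the semantics
under which a cut can jump by several clusters at once (as in a fourth cut
yielding 16 groups). Because tied or closely spaced heights can make
"`k` cuts" under-determined, explicit per-stage cluster counts are also
accepted (`cutsByClusterCounts()`, taking the greatest height reaching at
least the requested count). Background never enters the clustering; it is
appended as label 0 at every stage. The final stage is always the identity
on the original labels, so stage class counts are strictly increasing and
nested by construction.

## Training schedule and stopping

Each stage trains with per-pixel categorical cross-entropy. The loss is
reduced to the per-pixel *mean* (not the raw sum) so reported values are
comparable across patch sizes; under this reduction a uniform prediction
scores exactly `log C`, a convenient sanity anchor. The printed form of
the loss in the source swaps the naming of prediction and ground truth
(which would place the ground truth inside the logarithm); the standard
truth-weighted log-prediction form is the only trainable reading and is
what the package implements.

A stage ends when validation accuracy reaches a target (0.90 by default)
or when its epoch budget is exhausted, whichever comes first — the
published histories suggest budgets usually governed, so both controls are
exposed. For matched-budget comparisons (as in the packaged experiment)
the early-advance target is set to 1.0 so both arms consume identical
epoch totals. Seeds are separated by role: the network configuration seed
controls initialization, `globalSeed` controls data order per stage and
epoch, and each stage's head re-initialization derives its own stream.

## Evaluation

Patch predictions are summarized by the *hit ratio*: the fraction of
ground-truth target-class pixels predicted as that class. The denominator
is deliberately the truth foreground only — patches are single-class by
construction, and counting background agreement would reward trivial
background-heavy predictions. A patch is *definite* when its hit ratio
strictly exceeds 0.75 (a ratio of exactly 0.75 is indefinite). A class is
a *split case* for a model when more than half of its patches are
indefinite; the three-way set comparison (only model A, only model B,
both) operationalizes the qualitative Venn-diagram reading of which
classes remain hard. Per-patch reports rank predicted labels by pixel
count, name the top two, and pool the rest as "Other", ties at the cut
broken by ascending label id.

## The synthetic tray generator

The generator emulates the serving conditions the method targets — meals
on white plates on a gray tray — with controllable visual correlation:
each of `nFamilies` class families owns a base color on a circle of radius
`familyColorSpread` (RGB units) in the isoluminant plane around mid-gray,
and classes within a family perturb it by Gaussian offsets of standard
deviation `classColorSpread`. Blobs are superelliptical regions on white
plate discs, filled with the class color plus band-limited texture (at
wavelengths `textureScales`) and white noise, both of amplitude
`pixelNoise`; with `pixelNoise = 0` all blobs of a class are identical.
Placement uses a jittered grid, so packings either succeed or fail loudly.
Classes are dealt round-robin across trays, guaranteeing coverage and
near-uniform frequency.

Defaults are 3 families x 3 classes, 96x96 trays, 3 blobs per tray,
`familyColorSpread = 0.30`, `classColorSpread = 0.03` (a 10:1 ratio of
between- to within-family spread), `pixelNoise = 0.02` — conditions under
which the designed families are exactly recoverable (adjusted Rand index
1.0) from color-statistic prototypes and from the bottleneck prototypes of
a briefly trained model, which is what makes the pipeline testable end to
end without any download.

What the generator does *not* emulate: photometric variation between
trays (lighting, white balance), shape cues (all blobs are ellipses),
occlusion and touching foods, annotation noise, and class imbalance. A
passing curriculum experiment on this fixture therefore demonstrates the
mechanics and the direction of the effect, not full-scale performance on
photographs.

## The packaged experiment and its scale

The packaged comparison (test suite and `scripts/acceptance.R`) uses a
deliberately small instance chosen to keep a full three-seed run in the
minutes range on one CPU core: 24 training and 12 test trays (72/36
patches), 64x64 patches, a tiny U-Net (base 8, depth 3 — 18 convolutions,
64 bottleneck channels), batch size 4, and a two-stage curriculum
(families + background, `C = 4`, 8 epochs; all classes + background,
`C = 10`, 10 epochs) against a conventional run of the matched 18 epochs.
Under these conditions the sequential schedule matches conventional test
accuracy (median over three seeds, within one accuracy point) and starts
its final stage at a higher first-epoch training accuracy than the
conventional run's first epoch — the scaled-down analogue of the
better-start phenomenon. Full-scale quantities (66-way training on a
thousand trays for tens of epochs) are out of scope for a CPU-bound
package and are not asserted anywhere.

## Numerical choices and degenerate inputs

* Tied link heights are grouped with a relative tolerance of `1e-8` when
  cutting; merge tie-breaks follow the lowest-index-pair convention, so
  dendrograms are deterministic.
* Predicted probabilities are clamped at `1e-12` inside the loss to keep
  `log` finite; softmax subtracts the per-pixel maximum before
  exponentiation.
* `cutAtHeight` severs links *above* the height (links at exactly the
  height are kept); `cutsByGreatestLinks` cuts infinitesimally *below*
  each selected height.
* Empty inputs error early and descriptively: empty pair lists cannot be
  split, classes without patches cannot be sampled or expanded, masks with
  labels unknown to a stage name the offending label.
* Class ids must be dense (`1..n`) to build a trainable label hierarchy;
  sparse id sets are rejected rather than silently re-indexed.

## Known limitations

* The in-package network is CPU-bound and single-threaded beyond BLAS;
  it is sized for method research and testing, not production training.
* Masks persist as 8-bit PNGs, capping class ids at 255.
* The curriculum experiment's margins at desk scale are small; the
  packaged assertions are on medians across seeds for that reason.
* Only flip/rotation augmentation is implemented — no photometric
  augmentation, which matters for real photographs.
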