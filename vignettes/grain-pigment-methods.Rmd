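---
title: "Determining barley grain pigment composition from dish images"
author: "grainPigment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining barley grain pigment composition from dish images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Barley seed coats accumulate two pigment families. Anthocyanins give blue
and purple coloration; melanin gives gray and black. Either, both, or
neither may be present in a given accession, and the two dark phenotypes
are hard to tell apart by eye, while the chemical assays that settle the
question (acidified-methanol extraction for anthocyanins, alkaline
extraction for melanin) are slow and destructive. `grainPigment`
implements an image-based alternative: photographs of a Petri dish filled
with 100–160 grains are classified into the four pigment-composition
classes `NP` (no pigments), `A` (anthocyanins), `M` (melanin) and `AM`
(both). The class code is equivalent to a pair of binary presence calls,
one per pigment, and every model in the package ultimately emits that
pair.

The pipeline has four stages: (1) segmentation of the grain-filled dish
region from the background; (2) extraction of 2,380 colour descriptors
over the masked grain pixels, with filtering and normalization; (3)
classification by one of four models; (4) evaluation with a pooled
binary-decision accuracy, confusion tables, and a hulled-versus-hulless
comparison.

## The synthetic data generator

Real photographs and their chemical ground truth are not shipped with the
package. Instead, `generateDataset()` renders dish images whose
statistical structure matches what the pipeline assumes:

* a light circular dish on a light background, densely packed with
  105–140 convex grains (filled ellipses on a jittered hexagonal lattice,
  bounded pairwise overlap, orientation jitter);
* four class palettes in HSV space — `NP` tan-yellow (high value,
  mid-low saturation), `A` purple-blue, `M` gray-black (low saturation
  and value), `AM` anthocyanin-like hues at melanin-like values, so that
  `A`/`AM` overlap in hue and `M`/`AM` overlap in value, the confusion
  structure seen in real accessions;
* a hull factor that shifts value up and saturation down *within* each
  class — the hull perturbs colour variation more than it moves class
  boundaries;
* per-accession palette jitter (deterministic in the accession seed), a
  per-grain lighting gradient, and per-pixel Gaussian noise
  (`sigma = 0.015` by default, a realistic sensor-noise scale for 8-bit
  images);
* exact ground-truth masks: the mask is the set of painted grain pixels,
  not an estimate. Nine replicates per accession re-randomize grain
  placement but never the palette.

The generator is a pure function of its parameters and seed. What it does
*not* emulate: real grain texture (awns, creases, specular highlights),
vignetting and camera optics, JPEG artefacts, or the long-tailed
variation of real germplasm panels. Passing tests on synthetic data
therefore demonstrate that the implementation recovers structure the
generator put in — not that the models would reach any particular
accuracy on photographs.

Within-class colour spread is a calibration choice, not a measured value:
the default palettes are well-separated, and `mode = "hard"` narrows the
`A`/`AM` and `M`/`AM` gaps for stress testing.

## Data partitioning

Splitting operates on accessions, never on images: all nine replicates of
an accession share its split, so no accession leaks across
train/validation/test. Stratification is by pigment class crossed with
hull status — the two factors the downstream analysis cares about.
Apportionment uses the largest-remainder rule at two levels: global split
targets are fixed first from the total accession count, then per-stratum
floors are filled, and remaining seats go to the largest per-stratum
remainders subject to the global targets (ties broken by the seeded
shuffle). The two-level scheme guarantees the global counts exactly — 79
accessions at fractions (0.6, 0.2, 0.2) always give 47/16/16 accessions
and, with complete replicates, 423/144/144 images — which a purely
per-stratum rounding would not. A holdout set is a designation (an
explicit accession list), not a fourth random fraction.

## Colour descriptors and filtering

For each of the 12 channels of RGB, HSV, CIELab and YCrCb, the registry
holds the channel mean, the channel SD, and a 196-bin histogram of
channel intensity normalized to sum to one — 198 values per channel,
2,376 in total — plus four whole-region descriptors (grayscale mean and
SD, dark-pixel fraction below gray 0.1, and the foreground's area
fraction of the frame), for exactly 2,380 descriptors. All channels are
rescaled to [0, 1] before statistics (Lab via L/100 and an affine map of
a and b) so that a single threshold is meaningful across colour spaces.
Descriptors are computed over mask-foreground pixels only and are
invariant to anything outside the mask.

Filtering applies three rules in a fixed order: drop columns constant
across all images; drop columns whose value is at or below 0.01 in
strictly more than 20 % of images (near-empty histogram bins); then scan
columns in registry order and drop any whose absolute Spearman rank
correlation with an already-retained column reaches 0.97
(first-retained-wins, average ranks for ties). The low-value rule is read
as *strictly more than* 20 % — the reading that removes uninformative
near-zero bins while keeping boundary cases. Filtering is idempotent and
deterministic. The number of retained features is dataset-specific and is
reported, not asserted.

Normalization is a column-wise z-score whose means and SDs are estimated
on training data and stored, so validation/test/holdout rows are
transformed with training statistics. The RF13 representation projects
the normalized matrix onto its top 13 principal components (variance
fractions are stored and non-increasing); 13 components is the package
default for the colour-descriptor forest.

## The four classifiers

All four models are implemented on a compact dense-tensor network stack
written for this package (compiled convolution/pooling kernels with
hand-derived backward passes; Adam with global-norm gradient clipping;
per-pixel across-channel normalization and leaky rectification inside
conv blocks). The encoder "families" (`resnet18`, `resnet34`,
`efficientnetb0`) are width presets of this compact stack (base widths
8, 10 and 8 channels, five down/upsampling stages) — scaled-down
topologies in the spirit of their namesakes, not weight-compatible
clones. All networks run at a configurable reduced resolution (64 px for
classifiers, 128 px for segmentation by default); full resolution is a
configuration change.

**RF13.** Filter → z-normalize → PCA(13) → random forest (500 trees) on
the 4-class label, with the entire transform fitted on training data
only. Scores for the two pigments are vote sums P(A)+P(AM) and
P(M)+P(AM).

**Residual CNN classifier.** Dish-region crops (bounding box of the mask,
small padding) are resized and passed through a stem convolution and
stages of residual blocks with channel doubling and spatial halving,
global average pooling, and a two-unit sigmoid output head trained with
per-output binary cross-entropy. Training uses full-batch Adam steps over
many epochs with dihedral (flip/transpose) augmentation — at this data
scale (tens of images) batched steps are what makes the classification
objective converge; single-image steps oscillate without learning.

**U-Net + classification head.** One network yields both a grain mask and
pigment scores: an encoder of residual blocks with max-pooling, a decoder
of nearest-upsampling + convolutions with skip connections, a 1×1 sigmoid
mask output, and a dense head on the global-average-pooled encoder
bottleneck. Training is a phased block-coordinate schedule of the joint
loss (segmentation BCE + Dice, plus `lambda` times the classification
BCE): first the encoder and head are optimized on the classification
term with full-batch steps (committing the bottleneck to carry the
colour-class signal — under segmentation-only pressure the deep encoder
relaxes to input-independent features, because this segmentation task is
solvable from shallow skips alone); then the decoder is fitted with
per-image steps while the encoder is frozen, reading the full-resolution
skip features; finally the head is consolidated by full-batch logistic
refinement over cached bottleneck descriptors, with the feature
standardization folded back into the dense weights. The classifier
phases use dihedral augmentation plus a small global colour jitter
(per-channel gain and brightness offset at the scale of the
accession-level palette variation), so the head generalizes across
accessions instead of memorizing exact palettes. Level-1 convolutions
stay at their random initialization throughout: dense random colour
projections are exactly what the decoder needs from the skip path.
With `lambda = 0` the classification phases are skipped and the model
degenerates to pure segmentation, the head keeping its initialization.

**Two-channel pigment segmentation.** A U-Net variant with a two-channel
sigmoid output, channel 1 segmenting pixels of anthocyanin-containing
grain and channel 2 melanin-containing grain. Supervision is
label-broadcast (all grain pixels inherit the accession's flags) — a
deliberate weak-label scheme, since per-pixel chemical truth does not
exist. Level-1 convolutions run un-normalized here
(`raw_level1`), because per-pixel colour classification needs absolute
colour amplitudes (the brightness difference between `A` and `AM`, for
instance) that per-pixel normalization would strip from the skip path.
Training uses per-image steps (the supervision is dense) with a stepped
learning-rate decay; the channel separation emerges late in training and
the decay consolidates it. The image-level call is `aggregatePixels()`:
a pigment is present iff its channel's positive-pixel fraction exceeds
`min_fraction`. The default 0 is the literal any-pixel rule; because a
single stray pixel flips the call, the threshold is exposed, and the
scaled-down evaluations in this package use `min_fraction = 0.01`.

**Decision rule.** `decideLabel()` flags a pigment present iff its score
is *strictly* greater than the threshold (default 0.5); both at or below
gives `NP`. The rule is monotone in each score.

## Evaluation

Each image contributes two binary decisions. `computeACC()` pools them:
ACC = (TP + TN) / (P + N) with P + N equal to twice the image count.
Because both pigments are scored on every image, the pooled ACC equals
the mean of the two per-pigment accuracies, and both views are reported,
along with the 4×4 confusion table (rows = truth, columns = prediction).
The hulled-versus-hulless comparison is a two-sided rank-sum test on
per-image correctness indicators; correctness is heavily tied, so the
test enumerates all group assignments exactly up to a pooled n of 20 and
uses the tie-corrected normal approximation above that.

## Numerical and design choices

* Segmentation loss is binary cross-entropy plus soft Dice — the standard
  pairing for class-imbalanced region segmentation. Optimizer settings
  (Adam, fixed or step-decayed rate, clipping at unit global norm) are
  config entries recorded with the model.
* Convolutions are same-padded, so mask output size equals input size;
  the five down/upsampling stages make valid input sizes the multiples
  of 32.
* Channel growth in the U-Net is capped at 8× the base width: the deep
  levels stay compact without losing receptive field.
* Masks resample with nearest-neighbour interpolation (values stay
  binary); images resample bilinearly.
* Degenerate inputs fail loudly: empty masks, empty manifests, polygons
  with fewer than three vertices, pigment masks without exactly two
  channels, and grain counts that cannot be packed into the dish are all
  errors, not warnings.
* Problem sizes in the tests and the acceptance script are deliberate
  desk-scale choices: 20 training images at 128 px for segmentation
  recovery, 16 accessions × 3 replicates at 64 px for the classifier
  recovery runs, three seeds with the median reported. These sizes are
  large enough for the recovery properties to be stable and small enough
  to run routinely.

## Known limitations

* The synthetic generator's realism gap (above) bounds what the tests can
  claim about photographs.
* Holdout accuracies on photographic datasets depend on those
  photographs and are out of scope here; the package provides the
  *procedures* and their structural constants exactly, and demonstrates
  recovery behaviour on synthetic data.
* The literal any-pixel rule is noise-fragile by construction; use
  `min_fraction` > 0 for robust calls.
* The compact network stack runs on one CPU; it is not a GPU framework,
  and full-resolution training is possible but slow.
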