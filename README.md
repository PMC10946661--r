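# grainPigment

Classification of barley grain pigment composition from dish images.

## The problem

The dark colour of barley (*Hordeum vulgare*) seed coats comes from two
pigment families: anthocyanins (blue/purple) and melanin (gray/black),
which can occur singly or together. Visually the dark phenotypes are
nearly indistinguishable, and the chemical assays that decide the question
are slow and destructive. This package determines the pigment composition
of an accession — one of the four classes `NP` (no pigments), `A`
(anthocyanins), `M` (melanin), `AM` (both), equivalently a pair of binary
presence calls — from RGB photographs of grains in a Petri dish.

It is aimed at grain-phenotyping and cereal-genetics groups who have a
camera and a dish protocol but not a spectrometer.

## What is in the package

* **Synthetic dish-image generator** with exact ground-truth masks: four
  pigment-class colour palettes, a hulled/hulless appearance factor, ~100–160
  grains per dish, nine replicate images per accession. Every downstream
  stage is trainable and testable without photographic data.
* **Grain-region segmentation**: a compact encoder–decoder network
  (convolution + pooling encoder, upsampling decoder, skip connections,
  sigmoid mask output), trained with binary cross-entropy + soft Dice.
* **Colour descriptors**: exactly 2,380 features per image over masked
  grain pixels — per-channel mean, SD and a 196-bin histogram for the 12
  channels of RGB / HSV / CIELab / YCrCb, plus four whole-region
  descriptors — followed by three filtering rules (constant columns;
  values ≤ 0.01 in > 20 % of images; pairwise |Spearman ρ| ≥ 0.97),
  z-normalization with stored training statistics, and PCA.
* **Four classifiers**:
  `RF13` (random forest on 13 principal components of the descriptors),
  a residual CNN on dish-region crops, a multi-task U-Net with a
  classification head on the encoder bottleneck, and a two-channel
  per-pixel pigment segmenter whose image-level call is the any-pixel rule
  (`aggregatePixels`, threshold configurable).
* **Evaluation**: pooled binary-decision accuracy
  ACC = (TP + TN) / (P + N) over the two decisions per image
  (P + N = 2 × images), per-pigment accuracies, 4×4 confusion tables, and
  an exact tie-aware rank-sum comparison of hulled vs hulless accuracy.
* **Pipeline orchestration** (`runPipeline`) from a single YAML/list
  config with per-stage derived seeds, plus a thin command-line front end
  (`exec/grainpigment`).
* **LabelMe support**: polygon annotation documents rasterize to masks by
  scanline fill; accession-level stratified splitting reproduces the
  47/16/16-accession (423/144/144-image) partition of a 79-accession
  panel for any seed.

All tensors and network kernels (im2col convolution, pooling, upsampling,
with hand-derived backward passes) are implemented in the package itself
(RcppArmadillo), so nothing beyond the declared R dependencies is needed.

## Worked example

```r
library(grainPigment)
manifest <- generateDataset(
  classCounts = c(NP = 4, A = 4, M = 4, AM = 4),
  config = renderConfig(image_size = 96, replicates_per_accession = 3),
  seed = 1, dir = tempfile("demo"), hulledFraction = 0.5)
manifest
#> GrainManifest: 48 images, 16 accessions
#>   classes:  A=12 AM=12 M=12 NP=12

manifest <- stratifiedSplit(manifest, c(0.6, 0.2, 0.2), seed = 1)
splitCounts(manifest)
#>   split accessions images
#> 1  test          3      9
#> 2 train         10     30
#> 3   val          3      9

train <- manifestSplit(manifest, "train")
test  <- manifestSplit(manifest, "test")
rf <- trainRF13(extractFeatures(train), seed = 1)
rf
#> RF13Model: 13 principal components of 32 retained descriptors, 500 trees

pred <- predictLabel(rf, extractFeatures(test))
computeACC(pred, manifestRecords(test)$pigment_label)
#> EvalReport: ACC = 1.000 (TP 6 + TN 12) / (P 6 + N 12)
#>   anthocyanin  acc 1.000
#>   melanin      acc 1.000
```

The manifest rows carry one record per image (accession, pigment label,
hull flag, replicate, image/mask paths, split). `extractFeatures` returns
a `SummarizedExperiment` of the 2,380 descriptors; `trainRF13` fits
filter → normalize → PCA(13) → forest with all transforms estimated on
training data only. The report pools the two binary pigment decisions of
each test image: here 9 images give P + N = 18 decisions, all correct.

The network models follow the same pattern, e.g.

```r
seg <- trainSegmenter(buildSegmenter(segmenterConfig(input_size = 128)),
                      train, manifestSplit(manifest, "val"))
mask <- predictMask(seg, readImageRGB(manifestRecords(test)$image_path[1]))
```

and `runPipeline(list(classifier = list(model_kind = "unet_classhead")))`
drives generate → split → train → predict → evaluate end to end.

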