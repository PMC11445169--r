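# dropclass

Label-free classification of microfluidic droplet images by cell count,
robust to the in-droplet nanobead column ("beadline") used by
droplet-based secretion immunoassays.

## The problem

Droplet-based microfluidic (DBMF) assays encapsulate cells in ~40 pL
water-in-oil droplets. Encapsulation is Poisson, so every assay yields a
mix of empty, single-cell and multiple-cell droplets, and downstream
per-cell measurements are only interpretable once each droplet is
classified as **Empty/0**, **Single/1** or **Multiple/2** from its
brightfield image. In secretion assays, paramagnetic nanobeads aligned by
a magnetic field form a dark vertical column through the droplet that
occludes cells and sprouts blob-like irregularities that mimic them —
defeating both conventional cell detectors and networks trained on
minimally processed images.

`dropclass` implements, in R with a compiled (RcppArmadillo) network
engine:

* a **beadline-suppressing preprocessing pipeline**: horizontal-edge
  Prewitt convolution (kernel `[+1 +1 +1; 0 0 0; -1 -1 -1]`, which nulls
  column-constant structure), a bisigmoidal contrast filter

  `p' = 24000 · ( 1/(1+e^{α₁}) + 1/(1+e^{−α₂}) − ½ )`,
  `α₁ = min((p − min + mean)/600, 700)`, `α₂ = min((p − max + mean)/600, 700)`,

  bilinear resize to 55×55 without anti-aliasing, affine normalization
  `(p − min)/(max − min) × 65535`, and a circular mask of radius
  (half-width − 5); plus the *minimal* control variant (resize +
  normalize only);
* a **residual-network classifier** (compact desk-scale variant by
  default; a 50-layer bottleneck variant with the same I/O contract)
  trained with categorical cross-entropy by mini-batch SGD — learning
  rate 0.001, 6 epochs, batch 160, stratified 95/5 split;
* the three **conventional baselines** it is compared against: circular
  Hough transform, maximally stable extremal regions (MSER), and a
  morphological segmentation sequence with linear structuring elements of
  length 15 ("dilatation");
* a **synthetic droplet generator** (droplet rim, beadline with blob
  irregularities, ring-shaped cells, neighbour-droplet arcs, sensor
  noise) with exact ground truth, making every stage testable without
  microscopy data;
* an **evaluation harness**: per-class accuracy, confusion matrices,
  confidence-threshold retention curves, Welch and paired t-tests.

## Worked example

```r
library(dropclass)

## a labelled synthetic training set: beadline droplets, 3 balanced classes
scene <- scene_config(beadline = TRUE)
train <- simulate_labeled_set(600, scene, seed = 11,
                              preprocess_cfg = preprocess_config())
test  <- simulate_labeled_set(150, scene, seed = 99,
                              preprocess_cfg = preprocess_config())

## train with the published recipe (lr 0.001, 6 epochs, batch 160, 95/5)
model <- train_classifier(train$x, train$y, train_config(seed = 5))
preds <- predict(model, test$x)
score_predictions(preds$label, test$y)
```

```
Evaluation report
  overall accuracy: 93.3% (n = 450)
  Empty/0     100.0%  (n = 150)
  Single/1     94.7%  (n = 150)
  Multiple/2   85.3%  (n = 150)
  confusion (rows = true, cols = predicted):
    predicted
true   0   1   2
   0 150   0   0
   1   7 142   1
   2   0  22 128
```

Empty droplets are recognised perfectly (after full preprocessing their
interior is exactly zero); the remaining errors concern cell-bearing
droplets — mostly one vs several cells, plus a few single cells occluded
enough by the beadline to read as empty. Restricting to confident predictions trades a
little retention for accuracy:

```r
retention_accuracy(preds, test$y, c(0, 75, 90))
#   threshold retained_fraction  accuracy
# 1         0         1.0000000  93.33333
# 2        75         0.7066667  98.42767
# 3        90         0.1466667 100.00000
```

The conventional counters on the same droplets (raw images) show why the
neural route is needed when beads are present:

```r
raw <- simulate_labeled_set(100, scene, seed = 42)
run_baseline(raw$x, raw$y, "hough")    # per-droplet counts + labels
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/dropclass`:

```sh
dropclass simulate --n-per-class 500 --beadline --seed 7 --out data/
dropclass train    --manifest data/manifest.csv --out model/ --seed 7
dropclass predict  --model model/ --manifest data/manifest.csv --out preds.csv
dropclass evaluate --preds preds.csv --manifest data/manifest.csv --out report.json
dropclass baseline --method hough --manifest data/manifest.csv --out hough.csv
dropclass sweep    --param epochs --values 2,6,10 --out sweep.csv
```

Every run writes a resolved-config JSON snapshot next to its outputs.
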