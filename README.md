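# glanceCount

Count the fruit in an RGB image at a glance — a single forward pass of a
convolutional network predicts the count directly, with no detection or
localization step — and train that network **entirely on synthetic
scenes** whose count labels are exact by construction.

The package is aimed at plant-phenotyping / yield-estimation work where
annotated real images are scarce: it bundles

* a parametric synthetic tomato-scene generator (cluttered green/brown
  blurred backgrounds, shaded circular fruit with overlap, foliage
  occluders, shadows, illumination fields) with exact per-scene counts and
  per-fruit records;
* a modified Inception-ResNet count-regression network and a compact CPU
  training engine — Xavier initialization, Adam at a constant 1e-3,
  mean-squared-error cost, dropout keeping 65 % of activations, batch
  normalization after every convolution, and exponential-moving-average
  weights for evaluation;
* the classical area-based counter (YCbCr chroma thresholding,
  morphological opening/closing, count = total fruit area / calibrated
  per-fruit area) and a two-conv/two-fc shallow network as baselines;
* the evaluation statistics used to compare them.

## The statistics at the core

For a predicted count *pc* and actual count *ac* ≥ 1, the per-image
accuracy is

    pa(%) = (1 − |pc − ac| / |ac|) × 100

which is 100 only at equality and deliberately unclamped below zero.
Method-level results are the mean of *pa* over a test split, the count MSE
and RMSE (real-valued predictions), and an ordinary least-squares
regression of predicted on actual counts with its R².  The area baseline's
unit area is calibrated by exhaustive search minimizing the total absolute
count error on calibration scenes.

## A worked example

The `smoke` profile exercises the whole pipeline — generate train/test
splits, train the deep and shallow networks, calibrate the area baseline,
evaluate all three on the same held-out split — in about a minute:

```r
library(glanceCount)
cfg <- runConfig("smoke", seed = 1)   # 200/50 scenes, 32 px, width 0.25
res <- runPipeline(cfg)
res$comparison
#>          method meanAccuracy     rmse
#> area       area     72.33489 6.298760
#> shallow shallow     61.41981 6.635671
#> deep       deep     47.41093 7.480150
```

Each row is one method's mean per-image accuracy (percent) and count RMSE
on the shared 50-scene test split.  At this toy scale the deep network has
far too few optimizer steps to converge, so the calibrated area counter
leads; at the `desk` scale below (4 000 training scenes at 64 px) the deep
network converges and ranks first:

```r
res <- runPipeline(runConfig("desk", seed = 1))  # minutes on one core
res$comparison
#>          method meanAccuracy     rmse
#> deep       deep     89.45786 2.277834
#> shallow shallow     84.70624 2.749609
#> area       area     66.73043 4.858756
res$reports$deep
#> EvalReport 'deep': 400 images, mean accuracy 89.46%, MSE 5.189,
#>   RMSE 2.278, R^2 0.963
```

The deep network ranks first and the area counter trails badly on these
overlapping, partially occluded scenes — area-based counting loses exactly
the fruit area that occlusion hides.  The shallow network performs
respectably *on synthetic data*; shallow networks collapse on real
images (a sim-to-real phenomenon), which synthetic-only evaluation
cannot show.

A scene, its exact label and its per-fruit records are directly
inspectable:

```r
sc <- renderScene(sceneConfig(imageSize = 64), seed = 7)
fruitCount(sc)        # exact count drawn in the scene
head(sceneFruits(sc)) # centers, radii, ripeness, visible fractions
```

## Command line

A thin wrapper over the exported functions ships in
`inst/scripts/glancecount`:

```sh
glancecount generate --config run.yaml --n 1000 --split train --out data --seed 1
glancecount train    --config run.yaml --train data --out ckpt
glancecount eval     --ckpt ckpt --data data --split test --out report.csv
glancecount baseline --calibrate data --config run.yaml --out baseline.json
glancecount run      --config run.yaml
```
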