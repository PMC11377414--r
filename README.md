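# cunet — connected dual U-Net for CT lung tumor segmentation with pseudo-PET guidance

`cunet` is an R implementation of a multitask segmentation model for
non-small-cell lung tumors on CT. PET contrast makes lung tumors easy to
localize but PET scans are costly and add radiation dose, and cohorts with
acquired PET usually lack expert tumor masks while mask-annotated cohorts
lack PET. The package addresses both problems at once:

* **Connected dual U-Net.** A first U-Net synthesizes a pseudo-PET image
  from the CT slice; a second U-Net segments the tumor from
  concat(CT, pseudo-PET), with the first network's decoder features
  concatenated into the matching-resolution encoder levels of the second
  (cross-network skip connections). Inference needs CT only.
* **Mean-teacher semi-supervised training.** The student is optimized on
  `L = w·C + H + F`, where `H` is the pseudo-PET mean-squared error on
  PET-paired studies (Data A), `F = focal + dice` is the segmentation loss
  on mask-labeled studies (Data B), and `C` is the consistency (MSE)
  between the student's pseudo-PET and a teacher's pseudo-PET computed on
  a randomly rotated view of the same Data B slice. The teacher is an
  exponential moving average of the student,
  `θ′ₜ = α·θ′ₜ₋₁ + (1−α)·θₜ` with `α = min(1 − 1/(step+1), 0.99)`, and
  `w = 0.1·exp(−5(1−T)²)`, `T = 1 − epoch/80` (clamped to [0, 1]).
* **Clustering-based tumor-area detection.** Slice predictions are
  expanded with quarter-turn rotations; on up to 21 slices around the
  middle tumor-positive slice the farthest positive-pixel pair
  `(x_l, y_l, x_r, y_r)` is extracted; 2-means clustering of these
  quadruples and a λ-expanded rectangle (λ = 50 px on the 512/288
  reference grid) around the majority cluster's mean points defines a
  region mask `U`; re-predicting on `CT × U` removes false positives far
  from the tumor.

The audience is methods researchers in medical image analysis: every
mechanism (network, backpropagation, Adam, EMA, schedules, detector,
metrics) is implemented natively in R/RcppArmadillo with no deep-learning
runtime, and a synthetic thorax-phantom generator makes the whole pipeline
trainable and testable on a laptop CPU with no external data. It is not a
clinical tool.

## Worked example

Desk-scale study: 25 synthetic phantom studies of eight 64×64 slices,
split into 10 PET-paired studies (Data A), 10 mask-labeled studies
(Data B), 2 validation and 3 test studies; base-width-8 model trained for
20 epochs.

```r
library(cunet)

cfg <- modelConfig(baseWidth = 8, depth = 5)
connectedUNet(cfg, seed = 1)
#> Connected dual U-Net
#> ModelConfig: baseWidth 8, depth 5 (widths 8/16/32/64/128), in 1 ch
#>   1,023,322 trainable parameters in 164 arrays

spec <- phantomSpec(imageSize = c(64, 64), nSlices = 8,
                    tumorRadiusRange = c(4, 9), seed = 100)
split <- makeABSplit(generatePhantomSeries(25, spec),
                     fractions = c(0.8, 0.1, 0.1), seed = 1)
run <- trainConnectedUNet(cfg, split$dataA, split$dataB, split$val,
                          epochs = 20, batchSize = 2, seed = 11)
run$checkpoint
#> Checkpoint (epoch 19): validation DSC 0.8210

pred  <- lapply(split$test, function(s) predictVolume(run$checkpoint, s$ct)$mask)
truth <- lapply(split$test, function(s) s$mask)
evaluateMasks(pred, truth)$aggregate
#>   metric      mean         sd
#> 1    dsc 0.8350662 0.01199305
#> 2    iou 0.7170179 0.01769247
#> 3   hd95 1.2761424 0.19526215
```

Held-out Dice ≈ 0.84 means the predicted tumor masks overlap the ground
truth well; HD95 ≈ 1.3 mm says the predicted boundaries sit about one
voxel from the true ones. Tumor-area detection then removes distant false
positives — here on a 48-slice phantom carrying a distractor blob with
exactly the tumor's CT intensity:

```r
fx <- generatePhantom(phantomSpec(imageSize = c(64, 64), nSlices = 48,
                                  tumorRadiusRange = c(5, 8),
                                  distractorProb = 1, seed = 777))
res <- refineVolume(run$checkpoint, fx@ct, lam = 12, seed = 5)
res$region
#> RegionMask: 64 x 64, 1088 px inside; P0 (14.9, 26.5), P0' (23, 33), lambda 12
outside <- array(1 - res$region@mask, dim(voxels(res$mask)))
sum(voxels(res$firstPass) * outside)   # 136  false-positive voxels before
sum(voxels(res$mask) * outside)        # 0    none after refinement
```

A thin command-line front end over the same functions ships at
`inst/cli/ctseg.R` (verbs `synth`, `train`, `predict`, `refine`,
`evaluate`, `params`).

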