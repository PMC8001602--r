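# nglseg

Detection of newly grown leaves (NGL) in very-high-resolution RGB canopy
imagery, for forest-monitoring researchers working with UAV scenes where
the targets of interest are tiny (a few pixels), rare (~3–4% of pixels)
and bright light green against a smooth canopy background.

The package implements, as tested R code with no external deep-learning
runtime:

* **Sparse enhancement (SE).** Each channel P is decomposed into a
  low-rank background L plus a sparse anomaly part S — either by GoDec
  (alternating rank-r truncated SVD and hard top-k thresholding, solving
  `min ‖P−L−S‖_F` s.t. `rank(L) ≤ r`, `‖S‖₀ ≤ k`) or by convex principal
  component pursuit (`min ‖L‖* + λ‖S‖₁` s.t. `P = L + S`, inexact ALM with
  singular-value thresholding). The enhanced image is `E = P + S`, which
  amplifies candidate targets and leaves the background unchanged.
* **Six segmentation networks** built from symbolic layer codes:
  SegNet (26 conv / 5 pool) and U-Net baselines, plus shallow hybrids
  3L-SN, 3L-USN, 2L-USN and 2L-Conv-USN that reduce pooling depth to 3 or
  2 and add skip concatenations so tiny-target detail survives. The full
  engine — im2col convolution, batch norm, max-pool, nearest upsampling,
  backprop, Adam — is in-package and gradient-checked.
* **Imbalance-aware losses**: CE, weighted CE (β ∈ (1,2)) and balanced CE
  `−mean[β·p·log p̂ + (1−β)(1−p)·log(1−p̂)]` with working default β = 0.99
  (positive/negative gradient-weight ratio 99).
* **Sliding-window tiling** (the study geometry: 289 overlapping training
  patches and 25 non-overlapping test patches from a 1300 × 1000 scene),
  prediction stitching, and **evaluation**: error matrix (Pa, Pb, Pc, Pd),
  accuracy, ROC/AUC, Cohen's kappa `K = (Po − Pe)/(1 − Pe)`, tri-color
  result maps (hits red, false alarms blue, misses yellow).
* A **seeded synthetic scene generator** (low-rank background + clustered
  bright-green disc targets) standing in for the non-deposited study
  areas, and an **experiment runner** for β- and kernel-sweeps with a CLI
  (`exec/nglseg`).

## Worked example

Train sparse-enhanced 3L-USN on one synthetic area and evaluate on a
second, unseen area (a few CPU-minutes):

```r
library(nglseg)
pair <- generatePairedAreas(syntheticSceneConfig(seed = 101),
                            syntheticSceneConfig(seed = 202))
cfg <- runConfig(models = "3l_usn", kernels = "godec", betas = 0.99,
  trainSpec = tileSpec(128, 96, 32, 24),   # window 128x96, strides 32x24
  testSpec  = tileSpec(128, 96, 128, 96),  # non-overlapping
  epochs = 2, batchSize = 2, learningRate = 2e-3, valFraction = 0,
  maxTrainPatches = 24, seed = 1)
runExperiment(cfg, pair$train, pair$test)
#>    model kernel beta      auc      tpr        fpr       acc     kappa
#> 1 3l_usn  godec 0.99 0.998934 0.997642 0.07288878 0.9296672 0.4787362
#>   epochsRun nTrainPatches
#> 1         2            24
```

Reading the row: on the held-out area the enhanced shallow network ranks
target pixels above background almost perfectly (AUC 0.999) and detects
99.8% of true NGL pixels; at the hard 0.5 threshold the β = 0.99 loss
buys that recall with a 7% false-positive rate, giving chance-corrected
agreement kappa 0.48 after only two epochs on 24 patches — far above the
kappa = 0 of any constant prediction (longer training sharpens the
threshold and raises kappa further).

Individual stages are exposed directly: `sparseEnhance()`,
`godecDecompose()` / `pcpDecompose()`, `extractPatches()` /
`stitchPredictions()`, `buildModel()` / `trainModel()` /
`predictScene()`, `confusionCounts()` / `cohensKappa()` / `rocAuc()` /
`renderResultMap()`.

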