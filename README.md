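# cobbQuant

Automated Cobb-angle quantification from anterior-posterior spine
radiographs, for image-analysis researchers and scientific programmers
working on scoliosis assessment pipelines.

The Cobb angle — the clinical severity measure of scoliosis — is the angle
between the superior endplate of the most-tilted vertebra above a curve and
the inferior endplate of the most-tilted vertebra below it. Given endplate
slopes `Z_i` (upper vertebra) and `Z_j` (lower vertebra) as dy/dx in image
coordinates, each pairwise angle is

    CA_ij = | atan( (Z_i - Z_j) / (1 + Z_i * Z_j) ) |

with the perpendicular case defined as 90°, and the Cobb angle is the
maximum over all ordered pairs. Severity follows the standard
categorization: [0,10) Normal, [10,20) Mild, [20,40] Moderate, >40 Severe.

The package implements the full measurement pipeline around that formula:

* **Enhancement** — weighted-channel grayscale conversion
  (0.21 R + 0.59 G + 0.20 B) and an adaptive spatial Wiener filter, plus a
  pixel-domain visual-information-fidelity (VIF) quality score;
* **Landmarks** — projection-based spine cropping, sliding-window center
  line and lateral boundary detection with degree-4 polynomial fits, and
  vertebra identification from summed zero-indicator projection
  histograms;
* **Segmentation** — a four-block convolutional encoder–decoder with skip
  connections and a bottleneck atrous-spatial-pyramid-pooling (ASPP)
  block, implemented from scratch on Rcpp kernels (im2col+GEMM
  convolution with dilation, batch norm, pooling, bilinear upsampling)
  with hand-propagated gradients and SGD training, and an optional atrous
  feature-pyramid module on the skip paths;
* **Geometry** — connected-component vertebra boxes (axis-aligned bounds
  and minimum-area oriented box), endplate-slope estimation, the Cobb
  angle and severity class;
* **Evaluation** — Dice/IoU/MSE, the pooled two-sample t-test, MAPE, and a
  k-fold cross-validation harness;
* **Phantoms** — a synthetic AP spine phantom generator with pixel-exact
  masks and a known, constructed Cobb angle, so every stage is testable
  and trainable without patient data.

## Worked example

```r
library(cobbQuant)

# a 17-vertebra phantom with a constructed 25-degree curve
ph <- generatePhantom(phantomSpec(targetCobb = 25, seed = 3))
ph
#> SpinePhantom: 1024x384 px, 17 vertebrae, Cobb 25.00 deg (TH08-LU05)

# enhancement -> vertebra boxes -> Cobb angle (ground-truth-mask bypass)
res <- runPipeline(list(ph), runConfig())
attr(res, "details")[[1]]$cobb
#> Cobb angle: 25.0 deg (Moderate)
#>   reference vertebrae: TH08 (#8) / LU05 (#17)

# agreement statistics on the bundled ten-radiograph reader study
tab <- cobbAgreementStudy()
tt <- twoSampleT(tab$autoAngle, tab$expertAngle)
mp <- mapeScore(actual = tab$expertAngle, predicted = tab$autoAngle)
sprintf("|t| = %.4f (df = %d), p = %.4f", abs(tt$statistic), tt$df, tt$p.value)
#> "|t| = 0.1713 (df = 18), p = 0.8659"
sprintf("MAPE = %.2f%%, accuracy = %.2f%%", mp$mape, mp$accuracy)
#> "MAPE = 3.87%, accuracy = 96.13%"
```

The phantom constructs a known curve; the pipeline recovers 25.0° and
classifies it Moderate. On the bundled reader study the automated and
expert angle columns are statistically indistinguishable (pooled t-test
p = 0.87) and agree to within a 3.9% mean absolute percentage error.

To train the segmentation network at desk scale (a few minutes on one
CPU) and segment with it:

```r
phs   <- phantomTrainingSet(40, seed = 100)
model <- buildModel(netConfig(), seed = 1)
model <- trainModel(model, phs, trainConfig(batchSize = 8, epochs = 10))
tail(trainingHistory(model), 1)      # held-out Dice per epoch
seg   <- segmentImage(model, phantomImage(phs[[1]]))
```

A thin command-line front end (`inst/cli/cobbquant`) wraps the same
functions: `simulate`, `enhance`, `landmarks`, `measure`, `segment`,
`train`, `run`, `compare`.

## Vignette

`vignettes/cobb-quantification.Rmd` documents the models, the tunable
parameters and their defaults, what the phantom generator does and does
not emulate, the numerical conventions, and the design decisions taken
where the method description left choices open.
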