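---
title: "Automated Cobb-angle quantification: models, parameters and design"
author: "cobbQuant"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Automated Cobb-angle quantification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobbQuant)
```

# The problem

Scoliosis severity is graded by the Cobb angle: on a frontal
(anterior-posterior) radiograph, the angle between the superior endplate of
the most-tilted vertebra above the curve apex and the inferior endplate of
the most-tilted vertebra below it. Manual measurement is slow and shows
reader-to-reader differences of several degrees. `cobbQuant` implements an
automated pipeline — enhancement, spine landmarking, vertebra segmentation,
box geometry — plus the statistics used to validate such pipelines, and a
synthetic phantom generator so every stage can be trained and verified
without patient data.

# The angle model

Each vertebra contributes two endplate slopes, expressed as $dy/dx$ in
image coordinates with $y$ pointing down. For an upper vertebra $i$ and a
lower vertebra $j$ the inter-endplate angle is

$$\mathrm{CA}_{ij} = \left| \arctan\!\frac{Z_i - Z_j}{1 + Z_i Z_j} \right|,$$

with the perpendicular case $Z_i Z_j = -1$ defined as 90 degrees; the Cobb
angle is the maximum over all ordered pairs ($i$ above $j$), using the
upper endplate of $i$ and the lower endplate of $j$. This is the standard
angle-between-lines identity; `cobbAngle()` verifies it in the tests
against an independent direction-vector oracle
($\arccos$ of the normalized dot product of $(1, Z_i)$ and $(1, Z_j)$).
Ties are broken toward the topmost pair, then the longest span, and an
`adjacentOnly` flag restricts the search to neighbouring vertebrae for
users who prefer that reading. Severity follows the Cobb-method
categorization: angles in $[0,10)$ Normal, $[10,20)$ Mild, $[20,40]$
Moderate, above 40 Severe. The printed class boundaries overlap at 10, 20
and 40; we resolve them half-open on the left and assign 40 to Moderate
because Severe is conventionally stated strictly as "> 40".

# Enhancement

Radiographs are first collapsed to one channel with weights red 0.21,
green 0.59, blue 0.20. The weights sum to 1.00 exactly and are applied as
printed, without renormalization. Enhancement is an adaptive spatial
Wiener filter: with local mean $\hat m_s$ and local variance
$\hat\delta_a^2$ over an odd window (default $3\times 3$, reflect
padding), estimated signal variance
$\hat\delta_s^2 = \max(0, \hat\delta_a^2 - \delta_r^2)$ and noise variance
$\delta_r^2$, each pixel becomes

$$\hat o = \hat m_s + \frac{\hat\delta_s^2}{\hat\delta_s^2 + \delta_r^2}
  (z - \hat m_s),$$

a shrinkage toward the local mean proportional to the local
signal-to-noise ratio. Where $\hat\delta_s^2 + \delta_r^2 = 0$ the output
is the local mean. When no noise variance is supplied it is estimated as
the mean of the local variances over the whole image — the classic
adaptive-Wiener convention; the parameter is overridable. Two identities
pin the implementation down: a constant image is a fixed point, and
$\delta_r^2 = 0$ makes the filter the identity.

Enhancement quality is scored with a pixel-domain visual information
fidelity (VIF) approximation: single-scale sliding $3\times 3$ blocks with
scalar Gaussian-scale-mixture mutual-information terms, the ratio of
summed information in (reference, processed) over (reference, reference
through the visual-noise channel), clamped to $[0,1]$. The full
wavelet-domain metric with vector GSM is out of scope; the pixel-domain
variant preserves the two properties the pipeline relies on (identity
scores 1; the score decreases monotonically with degradation).
`ccSrocc()` computes the Pearson and Spearman correlations of two score
sequences as a generic utility; the package does not bundle subjective
opinion scores to correlate against.

# Landmarks

The spine region is isolated by a deterministic projection crop: Otsu
thresholding, row/column foreground projections, 10% padding, with an
explicit-box escape hatch. (A learned spine detector would need labeled
detector training data; the projection crop is a deliberate substitution
and is exact on phantoms.)

The center line is tracked by sliding a $W \times H$ window (defaults
12 x 52 px) horizontally across the top of the crop, seating the first
reference point at the maximum-sum window center (ties: topmost then
leftmost), then descending one pixel at a time while re-centering within a
lateral distance $q$ (default 12 px). Every $r$-th center (default 5) is
kept and a degree-4 polynomial of column on row is fitted. Lateral
boundaries slide paired 12 x 5 px windows outward from the center at each
row and keep the midpoint with the largest inner-minus-outer intensity
difference, fitting a degree-4 polynomial per side; rows where a fit
crosses the center line are flagged and clamped at evaluation so
left < center < right always holds. Two carried parameters, $x = 36$ and
$p = 11$, are stored in `centerLineParams()` for completeness but take no
part in the procedures: no operational definition of them exists, so
giving them one would be invention.

Vertebrae are identified from summed zero-indicator projection
histograms: intensities are sampled along four equally spaced vertical
lines between the boundaries, sub-threshold values are zeroed, and the
summed histogram $S$ counts the lines that are dark at each row. Disc
gaps appear as ascending shifts of $S$. Three implementation choices make
this robust on curved spines and are worth stating explicitly:

* the per-line projections are re-binned with a tilt correction of
  $d \cdot \mathrm{d(col)/d(row)}$ rows (offset $d$ from the midline,
  derivative from the fitted center polynomial), because vertebrae sit
  perpendicular to the spine curve and an oblique disc crosses the four
  lines at different rows;
* the four lines span the central 40% of the inter-boundary band —
  vertebra tilt displaces a gap by (lateral offset) x tan(tilt) rows, so
  lines near the midline stay inside the gap band even at strong
  curvature;
* an ascending shift is significant when the rise of $S$ over a short lag
  reaches half the maximal rise and lands at a level where at least three
  of the four lines are dark, with non-maximum suppression within half a
  vertebra height; each cut row is then refined to the darkest row within
  an 18-row non-overlapping bin grid anchored at the lower spine boundary
  (the bin refinement is interpreted as refining, not replacing, the
  shift-detected reference points).

# Segmentation network

The segmentation model is a four-block convolutional encoder-decoder with
skip connections and a bottleneck atrous-spatial-pyramid-pooling (ASPP)
block. Encoder blocks stack conv-BN-ReLU layers with feature maps
(32, 32, 64), (64, 64, 128), then doubling of the subsampled maps capped
at 256, each block ending in 2 x 2 max pooling with a skip copy taken
before pooling. The bottleneck runs parallel branches — a 1 x 1
convolution, dilated 3 x 3 convolutions at atrous rates 2, 4 and 6, and an
image-pooling branch (global average pool, 1 x 1 convolution, broadcast) —
fused by a 1 x 1 convolution, followed by dropout (rate 0.20). The decoder
mirrors the encoder: bilinear 2x upsampling followed by a 3 x 3
convolution (transposed convolution was rejected in favour of
resize-then-convolve, which avoids checkerboard artifacts), concatenation
with the skip, and two conv-BN-ReLU layers. A 1 x 1 convolution and
sigmoid produce the per-pixel foreground probability. Batch normalization
sits after each convolution, before the ReLU.

There is no deep-learning framework underneath: convolution (im2col +
GEMM, with dilation), batch normalization, pooling and bilinear
upsampling are Rcpp kernels, evaluated over a static layer graph with
hand-propagated gradients that the test suite checks against central
differences. The convolution GEMMs run in single precision — the standard
numeric width for network training — while everything outside the
convolutions accumulates in double precision.

Training choices, where the published description was ambiguous:

* "L2-norm loss" is read as the pixelwise mean squared error between the
  sigmoid output and the binary mask; weight decay (the other reading of
  an L2 penalty) is available separately via `trainConfig(weightDecay=)`.
* The optimizer is stochastic gradient descent with momentum 0.9; a
  learning rate of 0.01 is the conventional companion of that optimizer
  and matches the published value. Gradient norms are clipped at 5.
* One seed in `trainConfig()` drives the train/validation split, epoch
  shuffling and dropout, so two runs with the same seed produce
  bit-identical loss curves.
* The relationship between the bottleneck ASPP and the atrous feature
  pyramid over the skip paths is not fixed by the source material; here
  the ASPP always sits in the bottleneck and the feature pyramid is an
  optional skip-path module (`netConfig(useFPN = TRUE)`, default off), so
  both structures are exercisable and the default model remains the plain
  skip-connection network bit for bit.

The full-scale configuration (batch 12, 120 epochs) is retained as the
documented default of `trainConfig()`; the package's own experiments run
at desk scale — 64 x 64 inputs, 40 phantoms, batch 8, 10 epochs — which
reaches a held-out Dice above 0.95 on phantoms in a few minutes of CPU
time. The single-sample overfit sanity check disables dropout: a
regularizer that fights memorization has no place in a test whose goal is
memorization.

# Phantoms: what they emulate, and what they do not

`generatePhantom()` renders a stack of bright rounded-corner rectangles
(vertebrae) along a straight, single-arc or S-shaped center line,
separated by darker disc gaps, over a noisy darker background, with a
lateral intensity falloff (default 30% of the contrast) emulating the
radiographic density ridge along the spine midline. Vertebra centers are
spaced by arc length along the curve so the perpendicular disc gap is
preserved where the curve runs oblique, and each vertebra sits
perpendicular to the local tangent. A cosine taper adds tilt
(+target/2 at the top, -target/2 at the bottom); its weight is solved so
the realized maximal endplate angle equals the requested Cobb angle, and
among the two solutions of that (convex) spread equation the profile
closest to the perpendicular alignment is kept. If a cramped stack
(small gaps, strong tilt) would fuse neighbouring bodies when rasterized,
the tilt profile is damped toward the perpendicular alignment until the
bodies render distinct — the ground truth always records the *realized*
angle, recomputed from the stored slopes with the same pairwise formula
the measurement stage uses, so phantom truth and measurement share one
angle definition while the test oracle remains an independent
direction-vector computation.

The default canvas is 1024 x 384 px with 96 x 44 px vertebral bodies,
matching the scale of a cropped AP radiograph where a vertebra spans well
over a hundred pixels. This is not cosmetic: endplate angles inferred
from a binary mask carry rasterization noise of roughly
$\pm\arctan(1/\mathrm{width})$, so unrealistically small vertebrae make
angle recovery quantization-limited rather than method-limited.

Phantoms deliberately omit ribs, organ shadows, exposure gradients,
cortical shells and pedicles. Passing the phantom suite therefore shows
that the geometry, enhancement and learning machinery are correct under
known ground truth; it does not certify clinical accuracy on real
radiographs, which the published full-scale experiments address with
expert annotations.

# Endplate slopes from masks

Two estimators are available in `extractVertebraBoxes()`. The default,
`slopeMethod = "moments"`, takes the component's principal-axis
orientation from second-order central moments and assigns it to both
endplates: it pools every pixel and is robust to the staircase noise of
rasterized masks (worst-case error well under half a degree at realistic
vertebra sizes). `slopeMethod = "edges"` fits each endplate separately by
least squares through the per-column outermost pixels, restricted to the
central 60% of the column extent so box corners do not bias the fit; it
is the right tool for wedge-shaped bodies whose endplates are not
parallel, but on near-rectangular bodies a single 1-px staircase step can
bias the fitted slope by a few degrees, which the pairwise maximum then
amplifies. The moment default was chosen after quantifying exactly that
failure mode; the oriented minimum-area box (rotating calipers over the
convex hull) is always reported alongside.

# Evaluation statistics

`maskIoU()`, `maskDice()` and `pixelMSE()` implement the standard overlap
and error metrics, with the convention that two empty masks score 1
(agreement on absence) and one empty mask scores 0; the identity
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ is enforced to
$10^{-12}$ in the tests. `twoSampleT()` is the pooled (equal-variance)
two-sample t-test with $n_1+n_2-2$ degrees of freedom and a two-tailed
p-value — the pooled form is used because the bundled ten-radiograph
agreement study reproduces its published statistic (|t| = 0.1713 at 18
degrees of freedom) only under pooling; `stats::t.test` serves as the
independent oracle in tests, never as the implementation. `mapeScore()`
computes the mean absolute percentage error with the *expert* readings as
the actual values in the denominator; that orientation reproduces the
published 3.86% / 96.13% accuracy on the bundled study (recomputing from
the printed angle columns gives 3.87% — rounding of the printed per-row
values explains the last digit). `crossValidate()` shuffles with a seed,
splits contiguously into k disjoint folds, and reports per-fold Dice, IoU
and MSE plus a mean-and-SD aggregate row.

Two published summary numbers are deliberately not reproduced: the
reader-study table's stated mean absolute difference (2.86 degrees) is
inconsistent with its own angle columns (which give 0.93), so the angle
columns are taken as authoritative; and the enhancement-study CC/SROCC
values have no stated comparison partner, so `ccSrocc()` is exposed as a
utility rather than pointed at an unknown reference.

# Degenerate inputs and numerical conventions

All coordinates are 1-based (row, column) with closed integer intervals,
the R convention; images are numeric matrices on the 0-255 scale, and
8-bit quantization happens only at file write. Constant images are
rejected wherever a maximum or a threshold would be undefined (center-line
seating, Otsu, VIF reference). Empty masks are an error for box
extraction; single-column components are an error for edge-fit slopes.
The Wiener filter guards the zero-variance case by returning the local
mean. The pipeline isolates per-case failures: a case that errors is
recorded with its message and never aborts the batch.

# Known limitations

* The landmark stage assumes one spine roughly vertical in the frame;
  double-major curve decomposition and vertebral rotation grading are out
  of scope.
* The vertebra identification loses accuracy when vertebra tilt times the
  half-band width approaches the disc-gap height; at the default phantom
  scale this begins beyond roughly 45 degrees of total curvature.
* The network trains at desk scale on phantoms; no pretrained weights for
  real radiographs ship with the package.
* The VIF approximation is single-scale and pixel-domain; absolute scores
  are not comparable with wavelet-domain implementations, only orderings.
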