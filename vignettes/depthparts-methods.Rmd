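---
title: "Feature-based body-part determination in depth maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based body-part determination in depth maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthparts)
```

## The problem

Automated conformation recording of dairy cattle from 3D cameras needs
to know, for every pixel of a depth map, which body part it lies on.
`depthparts` implements a feature-based approach: each foreground pixel
of a 640 x 480 integer-millimetre depth map is described by five
properties — row index, column index, depth, a mean-curvature score and
the local depth variance — and a supervised classifier assigns it to
one of eight body parts: head (He), rump (Ru), back (Ba), the foreleg
facing the camera (fFL), the averted foreleg (aFL), the facing hindleg
(fHL), the averted hindleg (aHL) and the udder (Ud). Two classifiers
are compared under identical protocols: a k-nearest-neighbour (kNN)
classifier with a cross-validated grid search over k, and a dense
feed-forward neural network with an architecture grid search.

Recordings come from a walking passage with three camera position
types: a side-view camera `S` mounted 0.6 m above ground with a
horizontal line of sight, and a top-view pair — the lower camera `N`
mounted normally and the upper camera `U` mounted upside down (base
up). The udder is not visible from `U`, so `U` data carry seven
response classes instead of eight.

Because the original barn recordings are not publicly available, the
package ships a synthetic scene generator that renders labelled
cow-like composites from exactly these camera geometries. Everything
downstream — features, balancing, classifiers, evaluation — operates
identically on real or synthetic depth maps.

## The five pixel features

For a pixel p with a complete 3 x 3 foreground neighbourhood (the
"nine-pixel-square"), the package computes:

* **row, col** — 0-based image coordinates;
* **depth** — the depth value in mm;
* **m_curv** — a mean-curvature score. The gradient $g$ and Hessian
  $H$ of the depth surface are estimated by central differences on the
  nine-pixel-square (unit pixel spacing), and
  $$ \mathrm{m\_curv} \;=\; \frac{g H g^{T} - |g|^2\,\mathrm{Tr}(H)}{2\,|g|^{3}} , $$
  with $\mathrm{Tr}(H)$ the sum of the diagonal elements. When
  $|g| = 0$ the expression is 0/0 and the score is defined as 0 — the
  natural continuation, and the value a flat patch must produce;
* **var** — the sample variance (denominator $n-1 = 8$) of the nine
  depth values.

Three discretisation choices deserve a note. First, central
differences are the simplest estimator fully determined by a 3 x 3
patch, and they are exact on quadratic surfaces — the package tests
this property directly. Second, units are deliberately mixed: depth is
in mm but the pixel grid has unit spacing, so $g$ is in mm/pixel. The
published worked examples of the feature table (curvature values like
0.50, 2.00, 3.00 and variances 0.1945 = 126/648, 0.1109 = 72/648) are
reproducible only with raw-unit derivatives and the $n-1$ variance;
both choices are therefore frozen. The features are MinMax-standardised
afterwards, so the unit convention does not leak into the classifiers.
Third, pixels whose patch touches the image border or a background
zero are excluded from the feature table; including them would
contaminate curvature and variance with the arbitrary zero encoding of
the background. How border patches were treated in the original data
is not documented; this exclusion is the package's own documented rule.

A useful closed form for intuition and testing: on the depth map of a
sphere, the score evaluates exactly to $-1/(2\rho)$, where $\rho$ is
the pixel distance from the cap centre — a pure shape score,
independent of the depth scale.

Labels can come from the synthetic renderer or from polygon
annotations; `labelByPolygons()` is a programmatic point-in-polygon
labeller (strict interior, even-odd rule, later polygons win on
overlap) replacing interactive polygon drawing.

## Standardisation and the hold-out

Each feature is mapped to $(x - \min)/(\max - \min)$; a constant
feature maps to 0, and values outside the fitted range are *not*
clipped. A 30% hold-out set is split off (stratified by class,
seeded) and used only for the final evaluation.

One ambiguity is resolved as a switch: the original description
standardises the full table and then splits off the hold-out, which
lets the hold-out influence the scaler. The pipeline default
(`scale_on_train = TRUE`) fits the scaler on the training portion
only; `scale_on_train = FALSE` reproduces the scale-then-split order.
For MinMax scaling the difference is limited to the per-feature
extremes and does not alter any ranking, but the default keeps the
hold-out untouched on principle.

## SMOTE balancing

Legs and udder occupy far fewer pixels than back and rump, so classes
are strongly unbalanced. The synthetic minority oversampling technique
generates, for a minority sample $x_i$, synthetic points
$x_{new} = x_i + \lambda\,(x_j - x_i)$ with $x_j$ one of the
`k_neighbors` nearest same-class neighbours (Euclidean) and
$\lambda \sim U[0,1]$, until every class reaches the majority count.
`k_neighbors` defaults to 5, the technique's canonical value (the
original study cites the technique and library without stating k).

SMOTE sees **training rows only**. The package enforces this
structurally rather than by convention: the balancing step is embedded
inside the cross-validation folds of the kNN grid search and inside
the validation split of the network trainer, so evaluation rows are
never oversampled and no synthetic point can leak across the split.

## kNN classification and the grid over k

Training stores the labelled points verbatim; prediction takes the
majority class among the k nearest stored points. Two tie situations
the original description leaves open are made deterministic: a tied
vote goes to the tied class owning the single nearest neighbour, and
an exact distance tie is broken towards the lower stored-row index.
The neighbour search is exact brute force (implemented in C++); at
desk scale nothing approximate is needed, and the tie rules make the
output reproducible bit for bit.

k is tuned over {1, ..., 20} by five-fold cross-validation: the
training table is split into five equally large random parts, SMOTE is
applied to the four training parts only, and the accuracy on the
untouched fifth part is averaged over folds. Equal mean accuracies
resolve to the smallest k. If the plain random split strands a class
(fewer than two training samples in some fold), the split is redrawn
stratified with a warning. The neighbour lists are computed once per
fold at the largest k and reused for all smaller k, which makes the
20-point grid essentially free.

## The neural networks

The network is a plain stack of dense layers: 5 inputs, ReLU hidden
layers of equal width, softmax output with 7 (`U`) or 8 (`N`, `S`)
nodes. A 15% dropout layer follows every second hidden layer
(hidden layers 2, 4, ...), active only during training. The
architecture grid spans 0–16 hidden layers and widths
{10, 50, 100, 150, 200, 250, 300} — 119 cells
(`fullNnGrid()`); the selected architecture minimises the best
validation loss, ties towards fewer layers, then fewer neurons.

Training follows the stated protocol where it is stated: 30% of the
training rows are split off for validation, SMOTE balances the
remaining 70%, the categorical cross entropy is minimised with Adam,
the learning rate decays linearly per epoch, and training stops once
five epochs pass without validation-loss improvement, returning the
best-epoch weights. Where the protocol is silent the package fixes
standard values, all configurable in `nnConfig()`: ReLU activations,
Glorot-uniform initialisation, initial learning rate 0.001, batch size
256, epoch cap 100 (30 in the desk-scale pipeline default), and a
learning-rate floor of lr0/100 so the linear decay never reaches zero.
Whether the original grid search retrained each cell with early
stopping or fixed epochs is unstated; the package uses early stopping
per cell, which is both cheaper and consistent with the selection
criterion.

Divergence (non-finite loss) raises a training-failure condition that
carries the history; the grid search records such cells and excludes
them from the argmin.

## Evaluation

Evaluation on the hold-out is one-vs-rest: for each class, TP/FP/FN/TN
counts give precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ and their
harmonic mean F1. A zero denominator yields 0 by convention, keeping
the metrics defined on degenerate folds. Overall performance is
summarised by the accuracy and the Hamming loss — per sample, the
fraction of the N class indicators on which the one-hot prediction and
truth disagree, averaged over samples. For single-label data every
error flips exactly two indicators, so
$\mathrm{Ha.loss} = 2\,(1-\mathrm{accuracy})/N$; this identity links
every published (accuracy, Hamming loss) pair and is the basis of the
package's worked-example tests. (One published pair, accuracy 0.888
with loss 0.027 at 8 classes, implies 0.028 at print precision —
presumably unrounded internals; the package notes it and does not
patch it.)

Kruskal–Wallis rank tests (delegated to `stats::kruskal.test`, with
H = 0 defined for the all-tied degenerate case) compare the pooled
per-class metrics between classification methods and between camera
positions.

Display conventions: accuracy and Hamming loss print to 3 decimals,
per-class metrics to 2, rounding half away from zero.

## The synthetic scene generator

The generator exists so the pipeline is testable end to end without
the unavailable recordings; it emulates structure, not photorealism.
A cow is a union of labelled quadric primitives — ellipsoids for head,
back (barrel), rump and udder, capped cylinders for the four legs —
scaled to a sacrum height drawn from the herd's documented range
(1.43–1.49 m) and a body length around 2.4 m, with a small seeded
shape jitter per animal. The legs lean outward by 14 degrees so their
lower parts clear the body silhouette, which is what makes them
visible to a top-view camera, and the udder is tucked under the widest
part of the rump: its invisibility from `U` is a genuine occlusion,
exercised by the renderer, not a label deletion.

Rendering casts one ray per pixel through a pinhole model (57 degree
horizontal field of view, 640 x 480) and takes the nearest analytic
ray–quadric intersection — no meshes or z-buffers, so a brute-force
per-primitive oracle can verify occlusion exactly, which the test
suite does on 32 x 32 crops. The stored value is the distance along
the optical axis in integer mm (z-depth, the depth-map convention),
with additive Gaussian noise of sigma 2 mm by default — small against
the 500–4000 mm working range but enough to make the variance feature
non-degenerate — rounded to 1 mm; out-of-range or miss pixels are
background 0 in both depth and label mask.

The top-view mounting height and pitch are not documented; the presets
fix `S` at (0.6 m, horizontal), `N` at 1.75 m looking down about 20
degrees, and `U` at 3.3 m looking down steeply (about 75 degrees),
chosen so that `S` and `N` see all eight parts, `U` sees all seven
non-udder parts, and the udder is strictly occluded from `U` for every
cow in the configured size range. These are configuration, not claims
about the original rig.

What passing tests on synthetic scenes do **not** show: robustness to
real-sensor artefacts (structured-light speckle, holes, motion blur,
segmentation residue), to animal pose variation, or to the published
absolute accuracies, which belong to the real herd data. The synthetic
study shows that the feature set separates body parts under the
assumed geometry and that every protocol component behaves as
specified.

## Desk-scale sizes

The default experiment (`runConfig()`) renders 3 cows per position,
samples about 11,000 eligible pixels per scene (about 1e5 feature rows
over the three positions), caps the grid-search table at 8,000 rows
and final classifier training at 20,000 rows (stratified thinning
before SMOTE), and uses a reduced NN grid (layers 1–2, widths
{10, 50}, 30-epoch cap). These sizes are the package's choice of a
desk-scale study that a laptop CPU completes in minutes;
`full_nn_grid = TRUE` and larger caps restore the full sweeps. All
randomness flows from one master seed through fixed per-stage offsets,
so any stage can be re-run in isolation and the whole experiment is
bit-reproducible.

```{r, eval = FALSE}
res <- runExperiment(runConfig(seed = 1))
res$positions$S$knn_report
```

## Known limitations

* The cow geometry is a coarse quadric composite; silhouette-adjacent
  curvature values are dominated by the primitive shapes, not by
  animal anatomy.
* The udder-occlusion guarantee for `U` is verified over the default
  size range; extreme configuration values (very flat `U` pitch, very
  small cows) can break it and are the user's responsibility.
* kNN prediction cost grows linearly with the stored-exemplar count;
  the caps keep it interactive, mirroring the published observation
  that kNN wins on accuracy but loses on runtime cost.
* The Hamming-loss/accuracy identity holds only for single-label
  one-hot data; genuinely multi-label extensions would need the full
  per-indicator mean, which `hammingLoss()` already computes.
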