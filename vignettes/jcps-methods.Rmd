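---
title: "Coarse-to-fine semi-supervised vessel-wall segmentation with jcps"
author: "jcps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine semi-supervised vessel-wall segmentation with jcps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jcps)
```

## The problem

Black-blood MR imaging of the carotid artery suppresses the blood signal,
so the lumen appears dark and the vessel wall as a brighter annulus. The
clinically relevant structure is the wall — the set difference between the
outer wall (lumen plus wall) and the lumen — whose thickening indicates
atherosclerotic plaque. Manual wall annotation is slow, so in practice
only a minority of slices in a 3D stack (around 20%) carry expert labels.
`jcps` implements a coarse-to-fine, semi-supervised pipeline for exactly
this regime, together with a synthetic phantom generator so that the whole
method can be exercised and tested without any clinical data.

The pipeline has three stages:

1. **Coarse localisation.** A dual-head encoder–pyramid–decoder network
   (in the DeepLab style: two pooling levels, parallel atrous convolutions
   plus a global-pooling branch, low-level feature fusion in the decoder)
   predicts on each full slice (a) a lumen/background classification and
   (b) the signed distance function (SDF) of the lumen. The lumen mask is
   post-processed (largest connected component), its center of gravity
   (first-order moment) is computed per slice, and the resulting track is
   repaired using the spatial continuity of the vessel.
2. **2D cross-pseudo supervision (CPS).** Fixed-size patches are cropped
   around the repaired centroids. Two U-Nets with identical architecture
   but different initialisations are trained on mixed labeled/unlabeled
   patch batches; each supervises the other with its argmax pseudo labels.
   After training, the ensemble argmax yields pseudo labels `S2D` for
   *every* slice.
3. **3D cross-pseudo supervision.** The volume is split into overlapping
   depth chunks, cropped in-plane at the 3D (pooled) center of gravity.
   Each chunk, concatenated with the one-hot `S2D` channels, feeds a pair
   of 3D U-Nets trained with four loss terms: supervision on the labeled
   slices, 3D CPS between the pair, pseudo-label supervision by `S2D` on
   unlabeled slices, and an inter-slice continuity loss. Chunk
   probabilities are stitched (mean in overlaps) and pasted back.

## Loss functions

The coarse stage combines the Focal Tversky classification loss

$$L_{FT} = (1 - L_T)^\gamma, \qquad
  L_T = \frac{|P \cap Y|}{|P \cap Y| + \alpha|P - Y| + \beta|Y - P|}$$

(soft set sizes; defaults $\alpha = 0.7$, $\beta = 0.3$, $\gamma = 0.7$,
which penalise false positives more strongly and focus training on hard
examples) with a mean-squared-error regression of the SDF, weighted by
homoscedastic task uncertainty:

$$L(\sigma_1, \sigma_2) = \frac{L_{FT}}{\sigma_1^2} +
  \frac{L_{SDF}}{\sigma_2^2} + \log \sigma_1\sigma_2 .$$

The noise scales are trained jointly with the network (in log-variance
parametrisation); at stationarity $\sigma_i^2 = 2L_i$, which the test
suite verifies by numeric minimisation.

The fine stages use cross-entropy $l_{ce}$ plus soft Dice $l_d$ for
supervision and cross-entropy against argmax pseudo labels for the
consistency terms:

* 2D: $L_{2D} = L_{2D}^s + \lambda_0 L_{2D}^{cps}$ with
  $L_{2D}^{cps} = l_{ce}(S_2, P_1) + l_{ce}(S_1, P_2)$.
* 3D: $L_{3D} = L_{3D}^s + \lambda_1 L_{3D}^{cps} + \lambda_2 L_{3D}^{ps}
  + \lambda_3 L_{3D}^{cs}$, where the pseudo-label term averages
  $l_{ce} + l_d$ against `S2D` over the unlabeled slices of the chunk and
  the continuity term penalises each prediction slice against the pseudo
  labels of its two neighbors.

The consistency weights follow the ramp-up schedule
$\lambda(t) = e^{-5(1-t)^2}$ in normalised training progress
$t \in [0,1]$ ($\lambda_0 = \lambda_1 = \lambda_3 = \lambda(t)$,
$\lambda_2 = 1$), so pseudo-label agreement only gains weight once the
networks have stabilised. Pseudo-label targets are constants: no gradient
flows through an argmax. Argmax ties break toward the lowest class index,
and probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logs; both
choices make every loss value reproducible to the bit.

**Normalisation choices.** The SDF regression target is the exact signed
Euclidean distance map divided by the patch half-diagonal (and the SDF
head ends in a `tanh`), so regression targets live in $[-1, 1]$ and the
homoscedastic weighting is not dominated by scale. Per-slice
cross-entropy terms inside the 3D losses are pixel means, keeping the
magnitudes comparable across patch sizes; the two one-sided neighbor sums
of the continuity loss are summed as printed, which couples its scale to
the chunk depth and is absorbed by $\lambda_3$.

## Evaluation metrics

Per evaluated slice, with predicted/truth lumen areas $X_{AL}, Y_{AL}$,
outer-wall areas $X_{AW}, Y_{AW}$ and contours $X_O, Y_O$:

* `DSC`, `DSCL`, `DSCW`: Dice of the wall region, lumen, and outer wall;
* `Lad`, `Wad`: relative area errors $|X_A - Y_A| / Y_A$;
* `Nwid`: relative error of the normalized wall index
  $(A_W - A_L)/A_L$;
* `Hdol`, `Hdow`: symmetric Hausdorff distance between contours divided
  by the equivalent-circle radius $\sqrt{X_A/\pi}$ of the *predicted*
  region (as the score defines it; a flag selects truth-normalisation);
* the composite score
  $QS = 0.5\,DSC + 0.1(f(Lad) + f(Wad)) + 0.2 f(Nwid) +
  0.05(f(Hdol) + f(Hdow))$ with $f(x) = \max(0, 1-x)$.

Degenerate predicted slices (no lumen or no wall) receive Dice 0 and the
clamped worst-case value 2 for the affected indicators, so their $f(\cdot)$
contribution to QS is zero while per-case means stay finite. Per-case
aggregation is the unweighted mean over evaluated slices. Contours are
boundary pixel centers (8-connected boundary), since the package operates
on masks rather than polygonal annotations.

## The phantom generator

`generate_phantom()` emulates the geometry and contrast of an axial
black-blood carotid stack: a smooth random centerline (Gaussian steps,
moving-average smoothed, rounded to pixel centers), a lumen disk of
smoothly varying radius, a concentric wall annulus, and intensities drawn
as class mean plus Gaussian noise clipped to $[0,1]$ (defaults: lumen
0.15, background 0.35, wall 0.70, noise standard deviation 0.10 — a
moderate contrast-to-noise ratio in line with vessel-wall imaging, and
deliberately hard enough that a handful of labeled slices does not trivially
determine the segmentation). Optional *stenosis* scales the lumen radius
over a slice interval; optional *bifurcation* adds a second diverging
branch that appears in the image but not in the target-vessel labels —
exactly the failure mode the centroid-track repair must fix. Labels exist
on all slices; a uniformly random subset (`label_fraction`, default 0.2)
is marked as the labeled set A, with a contiguous-block option for
robustness experiments.

What the phantom does *not* model: MRI physics (coil profiles, bias
fields, flow artifacts), plaque texture, anisotropic voxel spacing, or
neighboring anatomy. Passing tests on the phantom therefore demonstrates
the correctness and the semi-supervised mechanics of the implementation,
not clinical performance.

## Networks and the built-in gradient engine

No deep-learning framework is a dependency: the package ships a compact
convolutional layer engine (C++ kernels for convolution, pooling and the
exact Euclidean distance transform; BLAS matrix products; hand-derived
reverse-mode gradients, validated against finite differences in the test
suite). All networks are size-configurable so tests run tiny instances
(base width 4, two levels) of the same architectures. Composite layers
are Conv–Norm–ReLU; normalisation uses per-sample spatial statistics
rather than cross-batch statistics, which keeps every forward pass
deterministic and independent of batch composition. Upsampling is
nearest-neighbor; downsampling is 2× max pooling. The fine-stage U-Nets
follow the halved-width recipe. Optimisers: Adam for the coarse stage
(learning rate 0.001, ×0.9 every 1000 iterations) and SGD with momentum
0.9, weight decay $10^{-4}$ and poly decay
$lr_0 (1 - \text{iter}/\text{max\_iter})^{0.9}$ from 0.01 for the fine
stages, as in the full-scale recipe.

## Geometry conventions

Coordinates are 1-based `(slice, row, col)`; centroids are real-valued
and rounded half-up only at crop time. Patch windows near the border are
shifted, never zero-padded, so patch statistics remain those of the true
image. Depth chunks start at stride `depth − overlap` (default overlap
`depth/2`), with the last chunk shifted to end at the final slice;
overlapping probabilities are averaged (a max-fusion flag exists) and
renormalised. The SDF boundary is the set of foreground pixels with a
4-neighbor in the background, distances are exact Euclidean between pixel
centers, and an all-background mask maps to the image diagonal. The
centroid-repair threshold defaults to $\tau = 24$ px — half the
half-width of the full-scale 96 px patch, guaranteeing that a vessel of
diameter below 64 px stays inside its patch even if the centroid is off
by $\tau$.

## Desk-scale study sizes

The full-scale recipe (720×720 slices, 96×96 patches, 32×96×96 chunks,
30 000 fine iterations) is preserved in the configuration defaults, but
all shipped studies run at desk scale, chosen so the complete pipeline
executes in minutes on one CPU: the default phantom study uses 40 slices
of 64×64 with 20% labels, 32×32 patches, 8-slice chunks with overlap 4,
tiny networks, and a few hundred iterations per stage. The `demo`
configuration is smaller still (16 slices of 48×48). These sizes are the
package's own choice of test conditions; the method itself is
size-agnostic.

## Design points that were genuinely open

* **What the 3D network consumes.** The fine-stage description can be
  read as feeding either the soft 2D confidence maps or the hard pseudo
  labels to the 3D network; figure-level descriptions and the text
  majority indicate the pseudo labels, so the package concatenates the
  one-hot foreground channels of `S2D` (the soft variant is one code path
  away, `chunk_input()`).
* **Which network produces `S2D`.** The ensemble mean of the trained 2D
  pair (argmax of the averaged softmax) — symmetric and deterministic.
* **Overlap fusion.** Mean of probabilities; the alternative max-fusion
  is behind a flag.
* **Narrow-region repair.** The centroid track is repaired (interpolation
  for missing entries, neighbor-interpolation replacement beyond
  $\tau$); copying adjacent-slice coarse masks is deliberately not the
  default.
* **Labeled-slice sampling law.** Uniform random over slices, exposed as
  configuration (plus a contiguous-block option), since only "randomly
  distributed" is known.

## Known limitations

* The engine is CPU-bound and single-threaded; it is meant for method
  study and testing, not clinical-scale training.
* Instance-style normalisation departs from classic batch normalisation;
  at these network widths it trains comparably and removes a source of
  nondeterminism.
* Evaluation requires ground-truth masks per evaluated slice; there is no
  contour-file ingestion.
* The phantom's difficulty is controlled by noise and geometry alone;
  conclusions about real MR data require real data.
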