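# jcps — joint 2D–3D cross-pseudo supervision for carotid vessel-wall segmentation

`jcps` is an R implementation of a coarse-to-fine, semi-supervised
segmentation pipeline for the carotid vessel wall in black-blood MR
volumes, built for the common clinical regime in which only ~20% of the
slices of a 3D stack carry manual labels. It is aimed at researchers in
medical image analysis who want a fully inspectable, CPU-only,
deterministic implementation of the method — including a synthetic
black-blood vessel phantom so every stage can be run and tested without
any clinical data.

## The method

Given a volume $I_{3D} \in \mathbb{R}^{D \times H \times W}$ with labels
on a slice subset $A$ (background / lumen / wall):

1. **Coarse stage.** A dual-head DeepLab-style network predicts per slice
   the lumen mask and its signed distance function (SDF), trained with the
   Focal Tversky loss
   $L_{FT} = (1 - L_T)^\gamma$, $L_T = |P{\cdot}Y| / (|P{\cdot}Y| +
   \alpha|P(1{-}Y)| + \beta|(1{-}P)Y|)$
   ($\alpha{=}0.7, \beta{=}0.3, \gamma{=}0.7$) plus an SDF regression,
   combined by homoscedastic uncertainty weighting
   $L = L_{FT}/\sigma_1^2 + L_{SDF}/\sigma_2^2 + \log\sigma_1\sigma_2$
   with learned $\sigma_i$. The vessel is localised by the first-order
   moment (center of gravity) of the post-processed lumen mask
   (largest connected component), and the per-slice centroid track is
   repaired using the vessel's spatial continuity.
2. **2D CPS stage.** Patches cropped at the centroids feed two U-Nets
   $f(\varphi_1), f(\varphi_2)$ (same architecture, different
   initialisation) trained on labeled + unlabeled patches with
   $L_{2D} = L_{2D}^s + \lambda_0\,[l_{ce}(S_2, P_1) + l_{ce}(S_1, P_2)]$,
   where $S_n = \arg\max P_n$ are stop-gradient pseudo labels and
   $\lambda_0 = e^{-5(1-t)^2}$ ramps up with training progress. The
   trained ensemble produces pseudo labels $S_{2D}$ for *every* slice.
3. **3D CPS stage.** Overlapping depth chunks, cropped in-plane at the
   pooled 3D centroid and concatenated with one-hot $S_{2D}$ channels,
   feed a pair of 3D U-Nets trained with
   $L_{3D} = L_{3D}^s + \lambda_1 L^{cps}_{3D} + \lambda_2 L^{ps}_{3D} +
   \lambda_3 L^{cs}_{3D}$ — supervision on labeled slices, 3D
   cross-pseudo supervision, pseudo-label supervision by $S_{2D}$ on
   unlabeled slices ($\lambda_2 = 1$), and an inter-slice continuity loss
   penalising each slice against its neighbors' pseudo labels. Chunk
   probabilities are stitched (mean in overlaps) into the final
   three-class segmentation.

Evaluation follows the challenge-style suite: Dice of wall / lumen /
outer wall, lumen and wall area differences, normalized-wall-index
difference, radius-normalized Hausdorff distances, and the composite
score $QS = 0.5\,DSC + 0.1(f(Lad){+}f(Wad)) + 0.2 f(Nwid) +
0.05(f(Hdol){+}f(Hdow))$, $f(x) = \max(0, 1-x)$.

Networks run on a small built-in convolutional engine (C++ kernels +
BLAS, hand-derived reverse-mode gradients, finite-difference-verified),
so the package has no deep-learning framework dependency and every run
is bit-reproducible from a seed on one CPU.

## Worked example

The `demo` configuration generates a 16-slice 48×48 black-blood phantom
with 6 labeled slices, trains all three stages at desk scale, segments
the volume and evaluates it against the phantom's exact ground truth:

```r
library(jcps)
res <- run_pipeline(demo_run_config(seed = 5), "demo_out")
res$metrics
#> Vessel-wall segmentation metrics (mean over 10 slices):
#>    DSC   DSCL   DSCW    Lad    Wad   Nwid   Hdol   Hdow     QS
#> 0.8964 0.8067 0.9143 0.3040 0.1169 0.5996 0.7748 0.6819 0.7152
```

Read: on the held-out (unlabeled) slices the wall region is segmented
with Dice 0.90, the lumen with 0.81 and the outer wall with 0.91; the
lumen area error is 30% and the wall area error 12%; the composite
quality score is 0.72 of a maximum 1. The output directory
contains the phantom (`volume.nii.gz`), the segmentation
(`segmentation.nii.gz`), per-iteration loss logs (CSV), the centroid
track, a PNG preview with contour overlay, the metrics JSON and a
manifest with MD5 checksums — rerunning the same configuration
reproduces the checksums byte for byte.

The same pipeline is scriptable from a shell via the thin CLI wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "jcps", package = "jcps"))')
Rscript "$CLI" generate --config run.yaml --out data
Rscript "$CLI" demo --seed 5 --out demo_out
```

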