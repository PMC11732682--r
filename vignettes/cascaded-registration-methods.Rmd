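---
title: "Cascaded deformable registration and multi-atlas segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded deformable registration and multi-atlas segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CascadeReg)
```

# The registration model

Given a moving image $X_{mv}$ and a fixed image $X_{fx}$ of size
$H \times W \times L$ on a domain $\Omega \subset \mathbb{R}^3$,
deformable registration seeks a spatial transformation
$\varphi : \mathbb{R}^3 \to \mathbb{R}^3$ such that the warped image

$$X_{wp} = X_{mv} \circ \varphi \approx X_{fx}.$$

CascadeReg represents $\varphi$ as the identity plus a dense displacement
field in voxel units and builds it incrementally with $n$ stacked
convolutional networks. Network $k$ receives the current warped image and
the fixed image and predicts a partial field $\varphi_k$; the partial
fields are **accumulated** — summed voxel-wise — and the running sum
resamples the *original* moving image:

$$X_{wp,n} = X_{mv} \circ \sum_{i=1}^{n} \varphi_i .$$

Accumulation is the load-bearing design choice: the alternative of warping
the previous warped image at every stage (functional composition, also
implemented as the `accumulate = FALSE` mode) degrades the image a little
at each trilinear resampling, and those losses compound. With accumulation
the moving image is interpolated exactly once per stage, always from its
original intensities — a contract the test suite asserts by counting
resampling operations. Successive cascades empirically specialise: the
first carries the smooth, low-spatial-frequency bulk of the deformation and
later ones add higher-frequency refinements (the suite checks that the
gradient energy of $\varphi_1$ does not exceed that of $\varphi_n$ in the
median over seeds).

## Training objective

Training is unsupervised. The loss is

$$\mathcal{L} = -CC(X_{fx}, X_{wp}) + \lambda \sum_{p \in \Omega} \lVert \nabla \varphi(p) \rVert^2,$$

with both terms evaluated **only on the final warped image and the final
accumulated field** — intermediate cascade outputs receive no supervision,
which couples the cascades into a single collaborating model rather than a
greedy pipeline.

The similarity term is a windowed local normalized cross-correlation: at
every voxel $p$, the squared covariance between the two images over the
$d^3$ window around $p$ is divided by the product of the two local sums of
squared deviations, so each window term lies in $[0,1]$ regardless of local
contrast or polarity. Identical images score $-1$. The multi-resolution
variant averages this loss over several window sizes (default
$d \in \{5,7,9,11\}$) with equal weight, exposing the objective to both
coarse structure and fine detail; the single-scale default is $d = 9$.

Numerical choices, fixed and documented here:

* **Means, not sums.** Both loss terms are means over their valid voxels,
  so $\lambda$ keeps one meaning across image sizes; $\lambda = 1$ by
  default, the value whose folding/overlap trade-off the test harness
  probes over $\lambda \in \{0.1, 1, 2\}$.
* **Valid windows only.** The NCC is restricted to voxels whose full $d^3$
  window fits inside the grid (moving-sum/integral-image evaluation);
  windows of near-constant intensity are stabilised by adding
  $\varepsilon = 10^{-5}$ to both denominator factors and contribute
  $\approx 0$.
* **Gradient operator.** The smoothness term uses forward differences,
  each of the nine partials averaged over its own support, so an affine
  field $\varphi_c = a\,x_c$ scores exactly $3a^2$; translations score 0.
* **Warping.** Trilinear interpolation for intensities, nearest-neighbour
  for labels. Out-of-domain samples replicate the border voxel ("clamp"),
  avoiding the dark halos that zero filling would feed into the local NCC
  at the brain edge; zero filling is available as an option.
* **Field units.** Fields are in voxels on the fixed grid; physical-mm
  spacing is carried through I/O metadata only. Saved fields are 4-D NIfTI
  with the x, y, z components on the last axis — our own convention,
  stated here because no standard exists.

## The contracted backbone

Each cascade is a 3-D encoder–decoder with skip connections: stride-2
convolutions halve the grid per encoder level, the decoder upsamples
trilinearly and concatenates the same-resolution encoder features. The
*contracted* design keeps hidden feature counts generous but **eliminates
all computation at the full grid size**: the decoder stops at half
resolution, the 3-channel field is emitted there and trilinearly upsampled
by 2 (vectors doubled for voxel-unit consistency). This trades a small
amount of fine-scale capacity for a large memory reduction, which is what
makes stacking many cascades affordable. Exact layer widths are
configuration, not architecture: the full-scale default is encoder
(16, 32, 64, 96) / decoder (96, 64, 32) at $128^3$; the desk profile uses
encoder (8, 16, 16) / decoder (16, 8) at $32^3$.

Two further contracts are deliberate: the field-emission convolutions are
zero-initialised, so an untrained cascade of any depth is exactly the
identity map (stabilising early training and giving tests an exact
invariant), and cascades do not share parameters.

All of this — convolutions via im2col plus BLAS gemm, trilinear
gather/scatter, leaky rectification (slope 0.2), Adam, and the full
reverse-mode gradient of the loss through warping, accumulation and every
layer — is implemented in this package (R orchestration over small C++
kernels) and verified against central finite differences in the test
suite, in both accumulation and composition modes.

## Optimization schedule

Adam with an exponentially decaying learning rate
$lr_{EP} = lr_0 \cdot e^{-3\,EP/EP_{max}}$. (The decay exponent is written
with a negative sign: a positive sign would grow the rate twenty-fold over
a run, contradicting its described decaying behaviour.) Full-scale
defaults: $EP_{max} = 500$ epochs of 100 iterations, batch size 2,
$lr_0 = 3 \cdot 10^{-4}$. After every epoch the *image-similarity term
alone* is evaluated on the validation pairs and the checkpoint is saved
when it improves; the regularization term takes no part in model
selection, so no labels or ground-truth fields are ever needed. Pair
sampling draws ordered pairs uniformly without replacement within each
epoch, self-pairs excluded. There is no gradient clipping; a non-finite
loss or field aborts with a diagnostic instead of training through it.

# Multi-atlas segmentation

Segmentation of a target volume proceeds in four steps: every annotated
atlas is registered to the target with the cascade model; the warped
atlases are ranked by whole-volume similarity to the target (Pearson NCC
on the target's foreground by default; MSE and a windowed SSIM are
available) and the best `nSelect` (default 10 of 20) are kept; their label
maps are propagated through the registration fields with nearest-neighbour
interpolation; and the propagated labels are fused.

Two fusion rules are provided. **Majority voting** takes the per-voxel
modal label. **Local weighted voting** weights atlas $k$'s vote at voxel
$i$ by $\omega_{k,i} = |m|^g$, where $m$ is the signed local NCC between
the warped atlas and the target over the $d^3$ window around $i$
(default $d = 9$), clamped below at zero before the gain exponent
$g$ (default 2) is applied. A vanishing weight floor makes voxels where no
atlas shows any positive local similarity fall back to a plain majority
vote. All ties — fusion argmax and modal ties alike — break to the lowest
class id, making every pipeline output deterministic. With $g = 0$ LWV
reduces exactly to majority voting, a reduction the tests assert.

Design points that were genuinely open: the selection similarity is
computed globally on the target foreground (no locality scale is implied
by ranking); the LWV similarity uses the *unsquared*, signed correlation
(the squared form would reward anti-correlated atlases); and $g$ per
metric is exposed as configuration rather than fixed.

# Evaluation metrics

Overlap is measured by the Dice coefficient
$DSC = 2|Y_{fx} \cap Y_{wp}| / (|Y_{fx}| + |Y_{wp}|)$ per class. Surface
agreement uses the one-sided percentile Hausdorff distance — the stated
percentile of the set of minimum Euclidean distances from every voxel of
one mask to the other, computed via an exact separable distance transform
with anisotropic spacing support — and HD95 takes the 95th percentile per
direction, then the maximum (a pooled-percentile variant is a flag; the
percentile interpolates linearly between order statistics, R type 7). All
mask voxels participate; no surface extraction is performed. Summary rows
report means with standard errors $\sigma/\sqrt{n}$ under the population
divisor $n$ (the $n{-}1$ divisor is a flag). Folding is quantified as the
percentage of interior voxels where $\det(I + \nabla\varphi) < 0$, with
central differences and border voxels excluded — one-sided differences at
the border systematically inflate folding estimates.

# The synthetic phantom generator

Real fetal-MRI cohorts cannot ship with a package, so the generator
produces the study conditions in miniature: nested ellipsoidal
"brain" phantoms with an outer CSF shell, a cortical ribbon whose
boundary carries a sinusoidal perturbation, a white-matter interior,
paired ventricles, cerebellum, thalamus and brain stem — eight classes in
total, each with a distinct mean intensity (T2-like contrast: fluid
bright, cortex dark) plus additive Gaussian noise (default sd 0.03) on the
foreground, clipped to $[0,1]$. A scalar `age` in $[0,1]$ scales the
overall head by $\pm 20\%$ and grows the cortical perturbation amplitude,
giving a monotone morphology axis that stands in for gestational age in
cohort experiments. Ground-truth deformations are Gaussian-smoothed white
noise, mean-centred per component and rescaled so the largest displacement
norm equals `maxDisp` exactly; at the default `maxDisp = 4`,
`smoothnessSigma = 4` they are fold-free, so a registration method should
be able to recover them with a diffeomorphic-looking field.

What the phantoms deliberately do not emulate: MRI physics (bias fields,
motion, multi-coil reconstruction), genuine anatomical variability beyond
the age axis, and inter-subject intensity harmonization. Passing the
phantom suite therefore demonstrates that the machinery — losses,
gradients, cascade recursion, fusion — is correct and that the method
recovers known smooth deformations at desk scale; it does not certify
performance on clinical data.

# Desk-scale experiment profile

The test suite and the acceptance script run every experiment at
$32^3$ with 3 cascades, the narrow backbone above, 30 epochs of 10
iterations, batch size 1, and base learning rate $6 \cdot 10^{-3}$
(the short schedule needs a larger step than the 500-epoch default; the
value was chosen for reliable convergence of the desk profile). A
parameter-recovery experiment trains on a single phantom pair with known
truth (`maxDisp = 4`, `smoothnessSigma = 4`) over three seeds and checks,
in the median: a foreground Dice gain of at least 0.15 over the
pre-registration overlap, a residual mapping error
$\lVert \varphi(x) + u(x + \varphi(x)) \rVert$ (equal to the
pre-registration displacement $\lVert u \rVert$ at $\varphi = 0$,
averaged over the foreground) that falls below that baseline, and zero
folding. Trend harnesses use the same image size and seeds: Dice non-decreasing and
folding non-increasing from 1 to 3 cascades at the 30-epoch budget;
folding non-increasing in $\lambda$ over $\{0.1, 1, 2\}$ (2-cascade
models, 20 epochs, consistent across arms); and a 2-cascade comparison of
multi-resolution against single-scale similarity training at equal
20-epoch budget, both arms scored on the averaged multi-scale NCC. The
multi-atlas experiment uses a 20-phantom cohort spanning ages
$[0.2, 0.9]$, NCC-selects 10 atlases per target and compares LWV against
majority voting and against the best single propagated atlas over five
targets. These problem sizes are the package's chosen desk-scale
conditions; the full-scale defaults remain available through the
configuration objects.

# Known limitations

* The backbone's exact layer widths at full scale are a configuration
  default, not a canonical architecture; no claim of optimality is made.
* Phantom anatomy is a deterministic function of the age parameter: two
  phantoms of equal age differ only in noise. Cohort experiments therefore
  contain near-twin atlases for targets whose age falls near a cohort grid
  point, which flatters single-atlas propagation and weakens the local
  similarity weights' ability to discriminate between well-registered
  atlases — real cohorts have no such twins.
* The benefit of the multi-resolution similarity loss grows with image
  size, cascade depth and training length; at the $32^3$ desk scale, where
  the smooth truth fields carry no fine-scale deformation, the comparison
  harness resolves no advantage over the single-scale loss.
* Composition (`accumulate = FALSE`) mode is fully differentiable and
  tested, but the shipped desk profile trains the accumulation mode only.
* Diffeomorphic integration (scaling-and-squaring) and field inversion are
  out of scope; folding is measured, not structurally prevented.
* Phantom experiments bound what the tests can certify about real MRI
  (see above); rigid pre-alignment is assumed done upstream.
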