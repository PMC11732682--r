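# CascadeReg

Unsupervised deformable registration of 3-D brain volumes with **cascaded
convolutional networks**, and a **weakly-supervised multi-atlas
segmentation** pipeline built on top of it. The package targets volumetric
(e.g. fetal brain MRI) studies where annotated data is scarce: registration
is trained without any labels, and segmentation needs only a small library
of annotated atlases.

## The method

Registration seeks a transformation `φ` with `X_wp = X_mv ∘ φ ≈ X_fx`. A
stack of `n` small encoder–decoder networks predicts incremental
displacement fields `φ_k`; the partial fields are **accumulated** so the
final warp is

```
X_wp,n = X_mv ∘ Σ_{i=1..n} φ_i
```

and the original moving image is resampled exactly once per stage —
avoiding the compounding interpolation losses of composed warps. Training
minimises, on the final output only,

```
L = −CC(X_fx, X_wp) + λ Σ_p ‖∇φ(p)‖²
```

where `CC` is a windowed local normalized cross-correlation, optionally
averaged over several window sizes (5–11 voxels) so the objective sees both
coarse and fine structure, and the second term is a gradient-norm smoothness
penalty that suppresses folding (negative Jacobian determinants). The
backbone is *contracted*: wide hidden feature maps, but no convolution at
the full grid size — the field is emitted at half resolution and upsampled,
which makes stacking many cascades affordable.

Segmentation registers every atlas to the target, ranks the warped atlases
by NCC with the target, keeps the best ten, propagates their labels, and
fuses them by local weighted voting: atlas `k`'s vote at voxel `i` carries
weight `ω_k,i = |m|^g` with `m` the local NCC over a `d³` window.

Everything — the 3-D convolutions, trilinear warping layers, the full
reverse-mode gradients, Adam, the losses, an exact Euclidean distance
transform for Hausdorff metrics, and a synthetic multi-tissue phantom
generator with ground-truth deformations — is implemented in the package
(R over small C++ kernels) and verified against brute-force oracles and
finite differences in the test suite.

## Worked example

Generate a synthetic pair with a known smooth deformation, train a
3-cascade model on it, and measure how much of the deformation was
recovered:

```r
library(CascadeReg)

prof  <- deskProfile(nCascades = 3, patchSizes = c(5, 7, 9, 11), seed = 1)
pair  <- makePair(phantomSpec(32, seed = 101),
                  deformationSpec(32, maxDisp = 4, smoothnessSigma = 4,
                                  seed = 201))
model <- initCascadeModel(prof$cascade, prof$loss, seed = 1)
fit   <- trainCascade(list(moving = pair$moving, fixed = pair$fixed),
                      model, prof$train)

reg    <- cascadeForward(fit, pair$moving, pair$fixed)
labels <- warpLabels(pair$movingLabels, reg$finalField)

cat("Dice before:", meanForegroundDice(pair$fixedLabels, pair$movingLabels),
    "\nDice after: ", meanForegroundDice(pair$fixedLabels, labels),
    "\nfolding %:  ", negFraction(jacobianReport(reg$finalField)), "\n")
```

```
Dice before: 0.7193098 
Dice after:  0.9261074 
folding %:   0 
```

The mean foreground Dice of the propagated labels rises from 0.72 to 0.93
after registration, with no folded voxels in the recovered field. The same
trained model slots into segmentation via
`segmentTarget(target, atlases, fit, fusionConfig())`, and the command-line
wrappers (`inst/cli/synth.R`, `train.R`, `register.R`, `evaluate.R`,
`segment.R`) expose the full synthesis → training → registration →
evaluation workflow to the shell.

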