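# entroseg

Two-phase variational level set segmentation of grey-scale images with
simultaneous multiplicative **bias field** (intensity inhomogeneity)
correction. Written for image-analysis work on modalities such as MRI where
a smooth shading field `b(x)` corrupts a piecewise-near-constant scene:

```
I(x) = b(x) J(x) + n(x)
```

with `J` the true image (`J ≈ c_i` within class `i`) and `n` additive
Gaussian noise.

The core is a **local-entropy-weighted local Gaussian distribution fitting
(LGDF) energy**: around every pixel `x`, a truncated Gaussian kernel `K`
scores the negative log-likelihood of the neighbouring intensities under
two Gaussians with bias-modulated means `b(x)·c_i`, and this local score is
weighted by the normalized local entropy `E_r(x) ∈ [0, 1]` of the
intensity-mass distribution in the window:

```
E_data = Σ_i λ_i Σ_x E_r(x) Σ_y K(x−y) [ log(√(2π) σ_i)
         + (I(y) − b(x) c_i)² / (2σ_i²) ] M_i(φ(y))
```

where `M₁ = H_ε(φ)`, `M₂ = 1 − H_ε(φ)` are smoothed memberships of the
level set function `φ`. A contour-length term `ν·Σ|∇H_ε(φ)|` and the
distance-regularization term `μ·Σ ½(|∇φ|−1)²` complete the energy.
Minimization alternates exact closed-form updates of the class means, the
bias field and the class variances with explicit gradient-flow evolution of
`φ`. Segmentation (`φ > 0` vs `φ ≤ 0`), the estimated bias field and the
bias-corrected image `J = I/b` come out of one run.

The package also ships a synthetic phantom generator (shapes × smooth bias
fields × seeded Gaussian noise), Dice/Jaccard overlap metrics, PNG/TIFF/PGM
and text-matrix I/O, and a command-line interface.

## Worked example

```r
library(entroseg)

# phantom: disk (120 on 40), +/-30% Gaussian-bump bias, heavy noise
sh <- make_shape("disk", 64, fg_value = 120, bg_value = 40, radius = 16)
ph <- compose_phantom(sh, make_bias(64, "gaussian_bump", 0.3),
                      noise_level = 0.05, seed = 11)

p <- model_params(kernel_sigma = 5, nu = 6, max_iters = 2000,
                  tol = 1e-3, tol_mode = "absolute")
res <- segment(ph$observed, p,
               init = list(kind = "circle", center = c(32.5, 32.5), radius = 20))
res
#> LGDF segmentation: 64 x 64 image, 2000 iterations (max iterations reached)
#>   class means      51.524 / 105.534
#>   class variances  3426 / 4482
#>   final energy     19464.1
#>   foreground (phi > 0) pixels: 3209

mask <- foreground_mask(res)          # class with the larger fitted mean
js(mask, ph$mask)                     # Jaccard overlap with ground truth
#> [1] 0.9154453
dsc(mask, ph$mask)                    # Dice coefficient
#> [1] 0.9558564
cor(as.vector(res$bias / mean(res$bias)),
    as.vector(ph$bias / mean(ph$bias)))   # bias field recovered up to scale
#> [1] 0.9643645
```

A Jaccard index of 0.92 means estimated object and truth overlap in 92% of
their union despite a noise standard deviation of ~57 grey levels on an
80-level contrast; the bias correlation of 0.96 says the smooth shading was
recovered up to the method's inherent global-scale ambiguity. The class
means (52 / 106) sit on the bias-corrected intensity scale; they are pulled
toward each other by the soft membership tails, which is expected — the
partition depends only on their midpoint.

Class labels in two-phase level set methods are interchangeable, so use
`foreground_mask()` (selects by fitted mean) when comparing against an
object mask. On noiseless, bias-free cartoons the free bias field makes the
joint model unidentifiable — see the methods vignette
(`vignettes/entroseg-methods.Rmd`) for this and other limitations, and for
why the phantom study uses `kernel_sigma = 5`, `nu = 6` and a preset
2000-iteration budget.

## Command line

```sh
Rscript inst/cli/entroseg.R phantom  --outdir ph --shape disk --noise 0.05 --seed 1
Rscript inst/cli/entroseg.R segment  --input ph/observed.txt --outdir out \
        --kernel-sigma 5 --nu 6 --max-iters 2000 --tol-mode absolute --seed 1
Rscript inst/cli/entroseg.R evaluate --mask out/mask.png --truth ph/mask.png
```

`segment` writes `mask.png`, `bias.txt`, `corrected.png`,
`energy_trace.tsv`, a parameter echo and a manifest; runs are
byte-reproducible given the same configuration and seed.

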