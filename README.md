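# spcombat

Superpixel ComBat harmonization of multi-scanner structural MRI.

## What it is for

Pooling T1-weighted MRI across scanners contaminates every downstream
measure with *scanner effects*: contrast shifts driven by acquisition
parameters (inversion time in particular), scanner-specific signal variance,
and smooth bias fields. Given matched **traveling-subject** data — the same
subjects scanned on every scanner, co-registered into one common space —
`spcombat` estimates voxelwise maps of the additive (location, γ) and
multiplicative (scale, δ) effect of each scanner, and removes them by a
linear back-transform. The audience is neuroimaging methodologists and
multi-site study teams who want *interpretable* harmonization (parametric
effect maps you can look at) rather than a black box.

## The model

Within each 3D superpixel `f` (a SLIC supervoxel of the subject's
cross-scanner average image, minimum 27 voxels), voxel `i` of scanner `j`
is modeled as

    Y_ijf = m_f + gamma_jf + delta_jf * eps_ijf,   eps_ijf ~ N(0, sigma_f^2)

so the standardized intensity `Z_ijf = (Y_ijf - m̂_f)/σ̂_f` is
`N(gamma_jf, delta_jf^2)`. Per-scanner effects are optionally stabilized by
empirical Bayes (priors `gamma_jf ~ N(mu_j, tau_j^2)`,
`delta_jf^2 ~ InvGamma(lambda_j, theta_j)`, method-of-moments hyperpriors,
iterated conditional posterior means). Harmonization applies

    Y*_ijf = sigma_f * (Z_ijf - gamma_jf) / delta_jf + m_f

voxelwise, using **leave-one-out** group-average maps so no subject is
harmonized with its own effects. A synthetic multi-scanner phantom generator
with known ground-truth effects, and the quality/evaluation metric suite
(SNR, CNR, CJV, WM2MAX, 3D SSIM, tissue-wise one-sample tests,
cross-scanner volume CVs, Cohen's d), make every stage testable offline.

## Worked example

```r
library(spcombat)

res <- run_pipeline(list(seed = 7,
  phantom = list(shape = c(48, 48, 48), n_subjects = 4,
                 bias_field = list(amplitude = 0.15, width = 16)),
  fit = list(eb_enabled = FALSE)))

head(res$raw_tissue$pooled[, c("scanner","tissue","mean_gamma","mean_delta","p_gamma")], 6)
#>   scanner tissue mean_gamma mean_delta  p_gamma
#> 1      GE    CSF      0.427      1.073 2.48e-07
#> 2      GE     GM     -0.444      1.078 2.45e-06
#> 3      GE     WM     -0.451      1.074 4.70e-05
#> 4 Philips    CSF     -0.234      0.897 1.36e-06
#> 5 Philips     GM      0.250      0.894 1.26e-05
#> 6 Philips     WM      0.262      0.900 3.18e-04
```

The table reads: on this phantom (whose scanners differ by inversion-time-
like contrast shifts, scale factors and bias fields), the GE-like scanner's
CSF signal sits 0.43 standardized units above the cross-scanner mean and
its GM/WM about 0.45 below, with ~7% excess variance (δ ≈ 1.07); the
one-sample p-values test each tissue mean against the normative values
γ = 0, δ = 1 across subjects. After leave-one-out harmonization the same
report shows the effects collapsing toward those normative values:

```r
mean(abs(res$raw_tissue$pooled$mean_gamma))          #> 0.22
mean(abs(res$residual$tissue$pooled$mean_gamma))     #> 0.03
```

Image-quality and feature-level metrics move the way harmonization should
move them — joint tissue variation down, cross-scanner structural
similarity up, volume estimates more consistent across scanners:

```
mean CJV raw:               0.331  -> harmonized: 0.318
mean cross-scanner SSIM:    0.9818 -> harmonized: 0.9865
GM-volume CV across scanners: 0.0107 -> 0.0011  (90% reduction)
```

Individual pieces are plain functions: `read_volume()` / `write_volume()`
(NIfTI-1), `resize_volume()`, `normalize_intensity()`, `slic3d()`,
`fit_subject()`, `render_maps()`, `average_maps()`, `harmonize_image()`,
`make_phantom()`, `ssim()`, `cjv()`, … A command-line front end is installed
at `inst/cli/spcombat` (subcommands `simulate`, `preprocess`, `parcellate`,
`fit`, `evaluate`, `pipeline`).

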