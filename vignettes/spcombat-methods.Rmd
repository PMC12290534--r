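---
title: "Superpixel ComBat harmonization: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixel ComBat harmonization: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcombat)
```

## The problem

When the same person is scanned on different MRI scanners, the resulting
T1-weighted images differ in ways that have nothing to do with anatomy:
tissue contrast shifts with acquisition parameters (notably inversion time),
signal variance differs with coil and reconstruction, and smooth
multiplicative bias fields differ between systems. For pooled multi-site
studies these *scanner effects* contaminate every downstream estimate, from
voxel intensities to segmented tissue volumes. `spcombat` estimates
interpretable additive (location) and multiplicative (scale) scanner-effect
maps from matched traveling-subject data — the same subjects scanned on all
scanners, co-registered into one common space — and removes them by a linear
voxelwise back-transform.

## The model

All images of a subject are assumed co-registered on one grid, background-
zeroed, and globally normalized so that the in-mask minimum maps to 0 and the
99th percentile to 1000. The subject's cross-scanner average image is
parcellated into 3D superpixels by SLIC; each superpixel is a *feature* `f`
and its voxels are the observations. Within feature `f`, voxel `i`, scanner
`j`:

$$Y_{ijf} = m_f + \gamma_{jf} + \delta_{jf}\,\varepsilon_{ijf},
\qquad \varepsilon_{ijf} \sim N(0, \sigma_f^2),$$

where `m_f` is the feature's overall mean, `gamma_jf` the additive location
effect of scanner `j`, and `delta_jf` the multiplicative scale effect.
Standardizing with the pooled estimates,
$Z_{ijf} = (Y_{ijf} - \hat m_f)/\hat\sigma_f \sim N(\gamma_{jf},
\delta_{jf}^2)$. The priors $\gamma_{jf} \sim N(\mu_j, \tau_j^2)$ and
$\delta_{jf}^2 \sim \mathrm{InvGamma}(\lambda_j, \theta_j)$ are fitted by
method of moments across features, and the per-feature effects are shrunk by
iterating the conditional posterior means to a fixed point — the standard
ComBat empirical-Bayes construction. Harmonization applies

$$Y^*_{ijf} = \frac{\hat\sigma_f\,(Z_{ijf} - \hat\gamma_{jf})}{\hat\delta_{jf}} + \hat m_f.$$

Because the design is matched (identical anatomy across scanners within a
subject), no biological covariates enter the model, and all parameters are
estimated separately per subject. Subject-level maps are averaged at the
group level; the maps applied to a given subject are averaged from the
*other* subjects (leave-one-out) to avoid circularity.

Two estimator details are deliberate choices the model statement leaves
open:

* $\hat\sigma_f$ is the pooled *within-scanner* residual SD (denominator
  $N_f - J$), not the grand SD, so `Z` has unit within-scanner variance when
  `delta = 1` — exactly the standardization the `Z` distribution above
  assumes.
* The iterated posterior means couple $\gamma^*$ and $\delta^{*2}$; residual
  location mismatch is absorbed into $\delta^{*2}$ during iteration, as in
  the reference ComBat implementations.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_superpixels` | `floor(N_mask/60)` | count | ~60-voxel features; yields roughly 13k superpixels on an MNI-1.5mm head mask |
| `min_size` | 27 | voxels | a 3×3×3 block is the smallest sample on which per-feature moments are trusted |
| `compactness` | `range/S` | intensity | see below; `S = (N_mask/K)^{1/3}` |
| `max_iter` (SLIC) | 10 | sweeps | standard SLIC budget; assignments stabilize earlier on phantoms |
| `sigma_floor` | 1e-3 | normalized intensity | degenerate (constant) features are floored and flagged, never divided by |
| `delta_floor` | 1e-2 | unitless | the back-transform never divides by a vanishing scale |
| `tol`, `max_iter` (EB) | 1e-6, 100 | — | fixed-point stopping; non-convergence is flagged, last iterate returned |
| `delta_mean` | geometric | — | group δ maps are averaged in the log domain: scale factors are reciprocal-symmetric (0.5 and 2 average to 1, not 1.25); switchable to arithmetic |
| `map_units` | z | — | group additive maps are stored in standardized units and enter the printed back-transform directly; an `intensity` mode applies literal subtract-then-divide |

### The compactness default

SLIC's distance is
$D = \sqrt{d_{int}^2 + (d_{sp}/S)^2\,c^2}$. The choice of `c` is a genuine
free parameter, and it interacts with the *estimator*, not just the
segmentation: if intensity dominates (`c` small), clusters select voxels of
similar noise texture, the within-superpixel SD underestimates the true
local SD, and standardized location effects are systematically inflated; if
space dominates entirely (`c` very large), superpixels straddle tissue
interfaces and the SD is inflated by mixture, diluting the effects. The
default `c = range/S` (the full in-mask intensity range over the grid step)
sits between the two regimes: within-tissue noise differences are small
against the spatial term, while tissue interfaces — whose contrast is on
the order of the full range — still repel clusters. The package's
parameter-recovery acceptance test measures the resulting tissue-mean bias
on phantoms; both failure modes were observed when sweeping `c` an order of
magnitude in either direction.

### Empirical Bayes: when to shrink

`eb_enabled = TRUE` (the default for map estimation) stabilizes per-feature
effects with ~60 observations each. The cost is the usual one: effects are
shrunk toward the scanner's across-feature mean $\mu_j$. When the true
effects are strongly tissue-structured — CSF shifted one way, GM/WM the
other, as inversion-time differences produce — that prior is misspecified
(multimodal), and tissue-mean estimates acquire a systematic bias
proportional to the shrink weight. The acceptance suite measures this
directly: the self-harmonization closure criterion passes exactly with EB
off and stays red at the 0.05 tolerance with EB on, and the
parameter-recovery criterion is therefore evaluated on the unshrunk
estimator (`eb_enabled = FALSE`, under which the starred effects equal the
raw effects by definition). The same reasoning makes raw effects the
default for residual re-estimation (`reestimate_residuals`): a residual
should be measured, not shrunk.

## The synthetic phantom: what it does and does not emulate

`make_phantom()` generates the matched multi-scanner cohorts every pipeline
stage is tested on, because real traveling-subject cohorts of this kind are
not publicly available. It emulates:

* 3-tissue (CSF/GM/WM) nested-ellipsoid "brains" with per-subject shape
  jitter, T1w-ordered tissue means (150/450/700 on the normalized scale);
* per-scanner, per-tissue location shifts (in SD units) and scale factors,
  with an inversion-time preset mapping longer TI to lower CSF and higher
  GM/WM signal;
* smooth multiplicative per-scanner bias fields (Gaussian blob, optional);
* additive Gaussian measurement noise, independent per scanner, on top of a
  per-voxel anatomy texture shared across scanners (so null effects with
  zero noise give byte-identical images — perfect co-registration by
  construction).

It does **not** emulate: Rician magnitude noise (the Gaussian approximation
holds on normalized high-SNR data, and is recorded as a simplification),
realistic cortical geometry or partial-volume mixtures, registration error,
motion, or acquisition artifacts. A green phantom test therefore
establishes algorithmic correctness and statistical calibration of the
estimators under the stated generative model — not robustness to
registration failure or anatomy-dependent segmentation bias.

The ground-truth sidecar reports the *standardized* effects the estimator
should recover, which differ from the programmed shifts by the pooling:
with pooled variance $\sigma_{pool,t}^2 = \sigma_t^2\,\overline{scale^2} +
noise^2$, the expected location effect of scanner `j` in tissue `t` is
$(shift_{jt} - \overline{shift_t})\,\sigma_t / \sigma_{pool,t}$ and the
scale effect is $\sqrt{scale_{jt}^2 \sigma_t^2 + noise^2} / \sigma_{pool,t}$.
These expectations hold for pure-tissue superpixels without bias field; the
generator-consistency test verifies them against empirical tissue moments.

Phantom sizes in the test-suite are desk-scale (36³–64³ with 1–8 subjects;
the default spec is 96³ with 8 subjects, and an MNI-sized preset exists) so
the whole suite runs in minutes on one CPU; the statistical assertions use
seeded draws with 3-standard-error bounds computed from the generating
parameters.

## Numerical choices

* **Normalization** anchors (min, P99) but does not clamp above 1000 — the
  hyperintense tail is exactly what the WM2MAX quality metric measures.
  Negative outputs are clamped to 0 (magnitude signal). The percentile uses
  R's default type-7 convention.
* **Resampling** uses separable B-splines (orders 0–5, default cubic) with
  the standard recursive prefilter, mirror boundaries, corner-aligned
  grids, and output shape `round(shape * spacing / target)`; an explicit
  `target_shape` pins the matrix instead, which is how a deviant
  acquisition is regridded onto a study matrix whose printed FOV doesn't
  quite equal the nominal product of shape and spacing.
* **SLIC ties and determinism**: the algorithm contains no randomness; the
  `seed` argument exists for provenance records. Orphan 26-components are
  absorbed into the adjacent label with the largest boundary contact (ties:
  lower label id); undersized labels merge into the 26-adjacent label with
  the closest mean intensity (ties: larger, then lower id).
* **Degenerate inputs**: constant features are sigma-floored and flagged;
  constant `delta2_raw` across features (exactly identical scanners) is a
  flagged error directing the user to `eb_enabled = FALSE`; neutral map
  voxels (γ=0, δ=1) pass through the harmonizer bit-exactly.
* **SSIM** uses Gaussian 7³ windows (σ = 1.5), C1 = (0.01·range)²,
  C2 = (0.03·range)², averaged over the mask; it is verified against a
  brute-force per-voxel implementation in the tests.
* **SNR** divides the tissue mean by the SD by default (scale-free, the
  convention under which published values of this metric have their usual
  magnitudes); a literal `variance` switch exists because the metric is
  sometimes stated as mean over variance. **WM2MAX** uses the 95th
  percentile of the whole in-head distribution as denominator (a
  WM-only denominator pins the metric near 1 by construction); both are
  config switches, not silent resolutions.

## Known limitations

* Registration, denoising and bias-field correction are out of scope;
  denoise/debias are pluggable hooks (identity default, bundled 3×3×3
  median reference plugin) and inputs are assumed co-registered. Group maps
  are applied in the common space only; warping them to native space is not
  implemented.
* The NIfTI-1 reader/writer is deliberately minimal: single-file `.nii`
  / `.nii.gz`, 3D only, spacing and description fields interpreted,
  orientation carried but never acted upon. It is round-trip-verified
  against an independent implementation in the tests.
* Pipeline configuration is JSON (no YAML parser is available in the
  supported dependency set); the structure is the same per-stage block
  layout.
* With very few subjects the leave-one-out group maps are noisy; the
  pipeline falls back to plain group averaging below 3 subjects.
* Empirical-Bayes shrinkage biases tissue-mean effect estimates when true
  effects are tissue-structured (see above); use raw effects for recovery
  and residual quantification, EB for stabilizing maps.
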