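# fuzzybias

Joint brain-MR tissue segmentation and bias-field (intensity
inhomogeneity) estimation by fuzzy clustering with local and nonlocal
constraints.

## The problem

Magnitude MR images are corrupted by two things at once: Rician noise and
a smooth multiplicative *bias field* caused by RF-coil nonuniformity,

```
X = b · X0 + N
```

where `X0` is the true piecewise-near-constant tissue image, `b` varies
smoothly around 1, and `N` is noise. Intensity-based clustering (fuzzy
c-means and its variants) fails on such data unless the bias is estimated
jointly with the segmentation. This package implements a joint model for
both, aimed at WM/GM/CSF brain-tissue segmentation, plus the classical
baselines it is compared against, a synthetic phantom generator with
ground truth, and Jaccard-based evaluation.

## The model

The segmentation minimizes, over memberships `u_ik` (summing to 1 per
pixel), prototypes `v_i` and bias field `b`,

```
J_m = Σ_i Σ_k u_ik^m Σ_{r∈Ω_k} K(r−k) ‖x_k − b_r v_i‖²
    + Σ_k a_k Σ_i u_ik (1 − u_ik^{m−1})
    + Σ_i Σ_k β_k u_ik^m Σ_{r∈Ω_k} K(r−k) ‖x̄_k − b_r v_i‖²
```

* `K` is a truncated Gaussian kernel over a window of radius ρ: the bias
  field enters only through kernel-weighted local averages, which is what
  makes a smooth multiplicative `b` identifiable.
* `x̄_k` is the nonlocal-means estimate of pixel k: a weighted average over
  the search window of radius `u`, with weights
  `S_kl ∝ exp(−‖patch_k − patch_l‖²_σ / h)` from Gaussian-profile patch
  distances (patch radius `s`). This injects global structure and is what
  gives the model its noise robustness.
* `β_k = (max w_k^u − min w_k^u)/max w_k^u` adapts the local/global balance
  per pixel: flat windows rely on the local term, structured windows on the
  nonlocal one.
* `a_k = α·min_i ‖x_k − v_i‖²` sharpens memberships towards the nearest
  prototype (the "improved fuzzy partitions" device).

All three update steps (membership, prototypes, bias) are closed-form
stationarity conditions; iteration stops when the maximum prototype change
drops below ε (default 0.001, fuzzifier m = 2). Setting `β ≡ 0, a ≡ 0`
recovers CLIC; additionally freezing `b ≡ 1` with a delta kernel recovers
GIFP_FCM, and `α → 0` standard FCM. BCFCM is provided as a separate
baseline. Labels, memberships, prototypes, the bias field, the corrected
image `x/b` and the objective trace are returned in one S4 object.

## Worked example

```r
library(fuzzybias)

# 64x64 three-tissue phantom: interleaved smooth regions, +/-20%
# Gaussian-bump bias, 5% Rician noise, with ground truth
ph  <- makePhantom(shape = c(64, 64), classes = 3, geometry = "blobs",
                   biasModel = "gaussian-bump", biasAmplitude = 0.2,
                   noisePercent = 5, seed = 42)

res <- segmentImage(observedImage(ph), method = "proposed", clusters = 3,
                    seed = 42)
res
#> SegmentationResult [proposed]
#>   grid: 64 x 64, 3 clusters
#>   prototypes: 0.2133, 0.5012, 0.7817
#>   sweeps: 5 (converged), final objective 12.5195
#>   bias field range: [0.8410, 1.2147]

evaluate(res, ph)
#> Jaccard similarity report
#>   per class: 0.9993, 0.9993, 1.0000
#>   mean: 0.9995
#>   bias-field Pearson r: 0.9684
```

The prototypes land on the true class means (0.2, 0.5, 0.8), the per-class
Jaccard similarity (overlap |A∩B|/|A∪B| after optimal label matching) is
essentially 1, and the estimated bias field tracks the simulated one
(Pearson r after mean-one normalization). The plain FCM baseline on the
same image reaches mean JS 0.9903 — the gap widens quickly at higher noise
and bias levels.

A thin command-line front end covers the same pipeline
(`inst/cli/fuzzybias segment|phantom|evaluate`); 2D PNG/TIFF and 2D/3D
NIfTI images are supported, with headers passed through to the outputs.

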