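---
title: "Joint fuzzy segmentation and bias-field estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint fuzzy segmentation and bias-field estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzybias)
```

# The model

Magnitude MR images follow $X = b\,X_0 + N$: a piecewise-near-constant
tissue image $X_0$, a smooth multiplicative bias field $b$ (RF-coil
nonuniformity, values near 1), and noise $N$ that is Rician in magnitude
images. `fuzzybias` estimates a fuzzy $c$-class segmentation and $b$
jointly by minimizing

$$J_m = \sum_{i=1}^{c}\sum_{k} u_{ik}^m \sum_{r\in\Omega_k} K(r-k)\,
        \lVert x_k - b_r v_i\rVert^2
      + \sum_k a_k \sum_i u_{ik}\!\left(1-u_{ik}^{m-1}\right)
      + \sum_{i}\sum_{k} \beta_k\, u_{ik}^m \sum_{r\in\Omega_k} K(r-k)\,
        \lVert \bar x_k - b_r v_i\rVert^2$$

subject to $\sum_i u_{ik}=1$, $0\le u_{ik}\le 1$, $m>1$. The three terms
are:

* **Local coupling.** $K$ is a truncated Gaussian over the square window
  $\Omega_k$ of radius $\rho$. Within a window the bias is approximately
  constant, so comparing $x_k$ against $b_r v_i$ for all window members
  both regularizes the memberships and makes $b$ identifiable. Expanding
  the square shows the window sums only ever involve
  $K \circledast b$ and $K \circledast b^2$, so every update is computed
  through two kernel smoothings of the bias field
  (`localWeightedSum()`), never per-pixel window loops.
* **Membership sharpening.** $a_k=\alpha\min_i\lVert x_k-v_i\rVert^2$
  (computed on raw intensities) is subtracted from every cluster's
  distance, pulling each pixel towards its nearest prototype — the
  "improved fuzzy partitions" device. It speeds convergence and crispens
  boundaries.
* **Nonlocal regularization.** $\bar x_k=\sum_{l\in w_k^u} S_{kl} x_l$ is
  the nonlocal-means estimate over a search window of radius $u$, with
  $S_{kl}\propto\exp(-\lVert x(N_k)-x(N_l)\rVert^2_\sigma/h)$ and patch
  distances weighted by a per-ring profile (below). Pixels whose
  surroundings look alike anywhere in the window support each other, which
  is what survives heavy noise. The per-pixel weight
  $\beta_k=(\max w_k^u-\min w_k^u)/\max w_k^u\in[0,1]$ (0 on flat or
  all-zero windows) turns the term off where the neighbourhood is already
  homogeneous.

Coordinate updates in closed form (memberships $\propto$ bracket$^{-1/(m-1)}$,
prototypes and bias as ratios of kernel-weighted sums) are iterated
u → v → b until the maximum prototype change falls below $\varepsilon$.

**Reductions.** $\beta\equiv 0, a\equiv 0$ gives CLIC (implemented as
exactly this configuration of the same engine); additionally $b\equiv 1$
with a delta kernel gives GIFP_FCM; additionally $a\equiv 0$ gives FCM.
BCFCM is a separate transcription of its own two update formulas. The test
suite verifies each reduction numerically against the independent
standalone implementations.

# The patch profile

The patch-distance weights depend only on each element's Chebyshev ring
$d_p$ within the $(2s+1)^2$ patch:

$$\sigma^{(p)} = \sum_{v=\max(d_p,1)}^{s} \frac{1}{(2v+1)^2\, s},$$

with patch coordinates taken 1-based so the centre has $d_p=0$. For
$s=1$ all nine weights equal $1/9$; in general they are non-increasing in
$d_p$ and sum to one — the identity the implementation is tested against
for $s=1..5$. In 3D the same per-ring weight is applied ring-wise over the
cubic patch.

# Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `clusters` | 4 | WM, GM, CSF + background for brain work |
| `m` | 2 | fuzzifier; the conventional choice for MR segmentation |
| `epsilon` | 0.001 | stop criterion on max prototype change |
| `kernelRho` | 4 px | local window radius; bias assumed locally constant at this scale |
| `kernelSigma` | ρ/2 | kernel width; covers the window without being flat |
| `patchRadius` (s) | 3 | patch radius of the nonlocal similarity |
| `searchRadius` (u) | 10 | nonlocal search radius |
| `alpha` | 0.9 | sharpening strength $a_k$, must be in (0, 1) |
| `alphaBcfcm` | 0.85 | BCFCM neighbour weight, 3×3 window ($N_\Omega=8$) |
| `h` | $2\hat\sigma^2$ | nonlocal decay (see below) |
| `normalizeBias` | TRUE | rescale b to mean 1 each sweep (see below) |

Two window radii exist deliberately: the *local kernel* radius ρ (the
scale on which the bias is treated as constant) and the *nonlocal search*
radius u (the scale on which self-similar structure is sought). Both are
independent flags.

**Choice of h.** $h$ controls how selective the patch similarity is.
Because the profile weights sum to one, the expected profile-weighted
distance between two patches differing only by i.i.d. noise of variance
$\sigma^2$ is $2\sigma^2$, independent of the patch size. The default
therefore sets $h = 2\hat\sigma^2$, the noise floor itself: patch
differences at the noise level keep weight $\sim e^{-1}$, genuinely
different structures are suppressed. Scaling $h$ by the patch area
instead would make the weights near-uniform over the search window and
the nonlocal mean a plain window average — which visibly flattens the
estimated bias field (its variation is smooth and would be averaged away
across the window). $\hat\sigma$ is a robust noise estimate: the MAD of
mirror-padded 3×3 Laplacian residuals divided by the operator's
coefficient norm (6). On strongly structured images it overestimates
somewhat (edges leak into the residuals), which errs on the smooth side;
`h` is a flag for users who want exact control.

**Bias identifiability.** The products $b_r v_i$ are invariant under
$b \to cb,\ v \to v/c$, so the raw field is only defined up to scale. By
default the field is renormalized to mean one over the mask after every
update and the prototypes are rescaled by the removed mean — the products,
hence the objective, are exactly unchanged, and the field becomes
comparable across runs and against simulated ground truth.

# Numerical conventions

* **Zero-distance / negative brackets.** Since $a_k$ subtracts a fraction
  of the minimum distance, a membership bracket can reach or cross zero.
  Brackets are clamped at $10^{-12}$ before the $-1/(m-1)$ power; pixels
  whose minimum bracket is at or below the clamp get crisp membership,
  split equally among ties. This is the exact constrained minimizer when a
  bracket is non-positive, and the standard convention for a pixel sitting
  on a prototype.
* **Borders.** Patches and kernel windows use mirror (symmetric, edge
  duplicated) padding; nonlocal *search* windows are clipped at the image
  border and the weights renormalized, so $\sum_l S_{kl}=1$ holds at every
  pixel including corners.
* **Sweep bookkeeping.** $a_k$ depends on the prototypes, which the
  closed-form derivation treats as a constant. It is therefore computed
  once per sweep, from the prototypes the sweep starts with, and held
  fixed through the u → v → b updates; the recorded objective uses the
  same $a_k$, so each sweep is a clean block of coordinate minimizations
  of one Lagrangian. (Descent of the recorded trace across sweeps is then
  an empirical property, not a theorem — the cross-sweep change of $a_k$
  can in principle raise the next value. Under the default stop criterion
  it is non-increasing on all tested fixtures; forcing
  $\varepsilon=10^{-8}$ exposes $10^{-5}$-scale upticks near convergence,
  and the same effect is measurable for GIFP_FCM.)
* **Caching.** The similarity weights depend only on the fixed input
  image, so $\bar x$ and $\beta$ are computed once before iterating, not
  per sweep. The dense weight table is never materialized in the pipeline;
  `similarityWeights()` exists for inspection and testing on small images.
* **Initialization.** All methods share the same seeded k-means++ +
  Lloyd initialization of the prototypes (ascending order), so
  comparisons between methods see identical starting points. The bias
  field starts at 1 everywhere.
* **Empty clusters.** A cluster whose update denominator vanishes is
  re-seeded from the pixel with the lowest maximum membership, with a
  warning; non-convergence at `maxIter` returns the last state with a
  warning rather than an error.

# The phantom generator

`makePhantom()` emulates the test regime the model is designed for:
piecewise-constant multi-tissue images (class means default to equal
spacing on [0.2, 0.8]), a smooth multiplicative bias field
(linear ramp, Gaussian bump or low-order polynomial, mean one, amplitude
up to ±0.8), and Rician noise realized as
$\sqrt{(x+n_1)^2+n_2^2}$ with the noise level given as a percentage of the
brightest class mean (the convention simulated-brain databases use).
Everything is deterministic given the seed.

Three geometries are provided. `nested-rings` (default) gives concentric
annuli with analytically checkable areas; `checker` gives repeating
blocks; `blobs` cuts a smooth seeded random field at equal-area quantiles,
producing interleaved compact regions with thin boundary bands — the
closest analogue of cortical tissue mixing. The benchmark and recovery
tests use `blobs` deliberately: a multiplicative bias is identifiable only
when several classes appear within a kernel window across the field's
range. Radially symmetric geometry under a centred radial bias is a
degenerate case — the class structure and the bias are confounded and any
intensity-based method attributes the bias to the class means.

What the phantoms do *not* emulate: partial-volume mixing at tissue
boundaries, anatomical shape priors, spatially varying noise, multi-coil
correlated noise, or 3D cortical topology. Passing the recovery tests
shows the estimator is correct under its own model assumptions at
realistic corruption levels — not that it reaches the same absolute
accuracy on clinical data.

# Test problem sizes

The oracle comparisons run on 6×6–16×16 images (where explicit-loop
transcriptions of every update are affordable and are compared to
1e-12–1e-10), descent and invariants on 24×24–32×32 phantoms over several
seeds, and the end-to-end recovery benchmark on 64×64 phantoms with ±20%
bias and 5–20% Rician noise — large enough for ~20 pixel-wide structures
and a smooth field, small enough to iterate quickly. The Rician/Rayleigh
calibration uses $10^6$ draws.

# Known limitations

* The bias scale is fixed by the mean-one convention; absolute bias units
  are not recovered (nor are they defined by the model).
* The adaptive $a_k$ makes the recorded objective only empirically
  monotone (see above).
* Exhaustive label matching in evaluation supports up to 8 classes.
* 3D volumes are supported throughout, but the per-ring patch profile is
  a 2D construction applied ring-wise in 3D (it no longer sums to one;
  the similarity normalization absorbs the constant).
* Single-channel intensities only; no multi-contrast coupling, no
  registration, no skull stripping (supply a brain mask instead).
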