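---
title: "Topological leaf-shape descriptors: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological leaf-shape descriptors: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaftopo)
```

## The model

`leaftopo` treats a leaf outline as a two-dimensional point cloud and
measures its topology across a density filtration. The chain is:

1. **Normalization.** The ordered closed polygon is resampled to
   `n_resample` points equally spaced by arc length, translated so the
   centroid of the resampled points is the origin, and scaled so the maximum
   centroid distance is 1. All shape information that survives is therefore
   translation-, rotation-, and scale-free up to raster effects.
2. **Rasterization.** The resampled outline is traced (Bresenham) onto a
   `resolution × resolution` grid over $[-1.1, 1.1]^2$; the foreground is the
   outline curve itself, not a filled region.
3. **Density.** Every outline pixel center $x$ receives the Gaussian density
   estimate $\Phi(x) = \frac1n \sum_i \frac{1}{\sqrt{2\pi}}
   e^{-\frac12 (\lVert x - y_i\rVert / h)^2}$ over the resampled points
   $y_i$. Density is high where outline passes close to itself: sinuses of
   lobes and serrations, leaflet attachments, crossings. The kernel constant
   is $1/\sqrt{2\pi}$ with no bandwidth factor in the normalizer, so $\Phi$
   is a dimensionless neighbor-density score bounded by $1/\sqrt{2\pi}$, not
   a probability density; we keep this form deliberately and expose it in
   `density_at()` so its closed-form values are testable.
4. **Localization.** Sixteen annulus kernels
   $K(x) = e^{-(d(x,y)-r)^2/(2\sigma^2)}$ centered on the centroid with radii
   $r_i = i/16$ and width $\sigma = 1/32$ multiply $\Phi$, isolating the
   shape band by band. Because the outline is scaled to maximum radius 1,
   the outermost ring always intersects the shape.
5. **Filtration.** For each localized field, 500 thresholds descend evenly
   from its maximum to its minimum (endpoints included). At each level the
   Euler characteristic of the superlevel set — 8-connected components minus
   4-connected holes — is recorded. The 16 curves are concatenated into an
   8,000-value descriptor.

Downstream, `fit_pca()` (centering only, no feature scaling: all entries are
Euler counts on a common scale) defines the morphospace; `lda_loo()`
classifies with leave-one-out cross-validation and equal class priors;
`permutation_test()` provides the chance reference; `family_variance_ranks()`
/ `diversity_residuals()` estimate family-level diversity.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_resample` | 2000 | points | makes pixel density reflect geometry, not digitization density; ~3 points per pixel at the default resolution |
| `resolution` | 512 | pixels/side | pixel size 0.0043 in normalized units; outline curvature at typical serration scales is resolved |
| `h` | 0.02 | normalized length | ≈ 4.7 pixel widths; small enough to keep serration-scale features distinct, large enough that the density field is smooth across the 1-pixel line width |
| `n_annuli` | 16 | — | distance bands fine enough to separate, e.g., leaflet tips from attachment zones |
| `sigma` | 1/32 | normalized length | half the annulus spacing: full radial coverage with moderate overlap between neighboring rings |
| `n_levels` | 500 | — | fine enough that component births/merges at distinct density values land on distinct levels |
| `domain` | `"contour"` | — | filter the density restricted to outline pixels (point-cloud reading); `"field"` filters the smooth density over the whole grid instead |

The threshold range is *per annulus per leaf* (that field's max down to its
min). Curves from different leaves therefore live on different absolute
threshold scales; this is intrinsic to the procedure and accepted. One
consequence, quantified below, is that the descriptor is more sensitive to
perturbations that change a local density *maximum* than to equally sized
perturbations elsewhere.

## Numerical choices

- **Connectivity.** 8-connected foreground with 4-connected background holes
  avoids the raster Jordan-curve paradox (a closed traced curve always
  encloses its interior). The convention is fixed, not configurable, so
  descriptors stay comparable. `euler_characteristic()` is a flood-fill
  implementation; the EC curve engine maintains the same quantity
  incrementally from local 2×2 block patterns, and the two agree exactly (the
  test suite checks both against a third, pure-R cubical pattern count).
- **Support.** The support of a localized field is the set of pixels with
  strictly positive density. A field that underflows to zero everywhere
  yields an all-zero curve; a constant positive field yields the EC of its
  full support at every level; the final threshold equals the minimum
  exactly, so the last superlevel set is always the full support.
- **Idempotent resampling.** A single equal-arc resampling pass is not a
  fixed point: chord-vs-arc deficits accumulate, and renormalizing a
  normalized contour would move points by ~10⁻⁴ on lobed outlines.
  `normalize_contour()` therefore iterates the resampling until cumulative
  arc positions are uniform to within 10⁻¹⁰ of the perimeter (a handful of
  iterations). Points may end up on chords of the input polyline; the
  displacement is $O((L/n)^2 \kappa)$, orders of magnitude below pixel size.
- **PCA signs.** Each loading vector is flipped so its largest-magnitude
  entry is positive, making scores reproducible across BLAS/LAPACK builds.
- **Permutation p-value.** Add-one estimator $(1 + \#\{null \ge obs\})/(B+1)$:
  never exactly zero, and equal to $1/(B+1)$ when no permutation reaches the
  observed accuracy.
- **Diversity conventions.** Variance ranks descend (1 = most variable) with
  average ties; sample variance ($n-1$) by default with a population option;
  families of size 1 are kept with variance 0 and flagged. The Wilcoxon
  signed-rank group test is exact for subsets of ≤ 25 families (zeros
  dropped), normal approximation above.
- **Singularities fail loudly.** A singular within-class covariance in LDA
  raises an error advising fewer components rather than silently
  regularizing; the size-correction regression refuses all-equal family
  counts (the full pipeline then still reports counts and median ranks, with
  missing residuals).

## The synthetic generator

`generate_blade()` produces polar outlines
$r(\theta) = 1 + A\cos(k\theta) + s\cos(f\theta)$, stretched by
`base_aspect` along one axis, sampled at 720 vertices, with optional i.i.d.
Gaussian coordinate noise (redrawn until the polygon is simple).
Closed-form control of lobe count and depth gives analytic expectations:
$A = 0$ with unit aspect is a circle (circularity ≥ 0.999), the moment
aspect ratio equals `base_aspect`, and solidity decreases monotonically in
$A$. `generate_compound()` builds palmate or pinnate leaves as boolean
unions (via `polyclip`) of ellipse leaflets around a central disk or along a
rachis strip, traced as one closed contour.

Two adjacent leaflets are always *crowded* (placed so they overlap). With
`hole = FALSE` the union absorbs the overlap and only the outer outline is
traced — what a scan of a flat leaf with touching leaflets shows. With
`hole = TRUE` the boundary loop of the overlap region is spliced into the
traced path: the outer outline is unchanged, but the raster now encloses an
extra background region, emulating the occlusion hole visible when leaflets
overlap. This makes the hole flag a *minimal* perturbation — the same leaf
plus an internal feature — which is the comparison the robustness property
needs. During design we measured the alternative (moving or splicing a whole
leaflet): it shifts per-annulus density maxima and, through the per-leaf
threshold rescaling, perturbs the descriptor as much as removing a leaflet
outright. The packaged fixture for robustness checks is the 5-leaflet
palmate leaf: with more leaflets the structural reference change (one
leaflet fewer out of many, all attachment angles shifting slightly) becomes
small enough to approach the occlusion artifact, so the margin of the
robustness comparison narrows as leaflet count grows.

The `"four-class"` preset (entire-elongated, five-lobed, serrated, and
7-leaflet palmate, with ±10% aspect jitter, ±15% lobe-depth jitter, and
coordinate noise of 0.003 blade units ≈ sub-pixel at the default raster)
represents clearly distinct architectures with realistic digitization noise.
Per-instance seeds derive deterministically from the master seed
(`seed + instance counter`), so datasets are byte-identical under a fixed
seed.

What the generator does *not* emulate: venation, petioles as distinct
structures, allometric covariation, margin microtexture, or the imaging
pipeline (thresholding, smoothing) of real scans. Passing tests on these
fixtures show the machinery is correct and that well-separated architectures
are recovered; they do not show field-realistic classification rates, which
on broad natural datasets are far below 100%.

A note on degenerate shapes: for a near-circular outline all contour mass
sits at radius ≈ 1, so only the outermost annuli carry signal and the
descriptor becomes sensitive to small aspect fluctuations. Real leaves (and
the presets) have elongation or internal structure that spreads the outline
across radii; perfectly circular "leaves" are the least informative case for
an annulus-localized descriptor.

## Problem sizes

The test suite exercises the full default pipeline (512 grid, 2,000 points,
16 × 500 descriptor) wherever a property depends on those defaults
(descriptor structure, rotation invariance, occlusion robustness, the
four-class study with 30 leaves per class and a 999-permutation null), and
smaller grids (128–192 pixels, 8 annuli, 60 levels) for pipeline plumbing
where the property under test is size-independent. A single default
descriptor takes ~0.1 s; the four-class study end to end takes ~30 s on one
CPU.

## Known limitations

- The per-annulus threshold rescaling means absolute curve values are not
  comparable across leaves level-by-level in physical density units; only
  the full descriptor (and distances on it) is the intended object.
- Rotation invariance is exact at multiples of 90° and approximate
  otherwise (raster effect only; relative L2 ≈ 0.1 at 45° and the default
  resolution).
- The `"field"` filtration domain evaluates the density on every grid pixel
  and is an order of magnitude slower; it is provided for comparison, not
  tuned.
- Descriptor distances weight all annuli equally; no curve normalization or
  annulus weighting is applied before concatenation.
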