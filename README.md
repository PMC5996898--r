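# leaftopo

Topological morphometrics for leaf outlines.

Leaves across seed plants are too disparate for the classical comprehensive
shape methods: landmarks need homologous points, and pseudo-landmarks and
elliptical Fourier descriptors need features that correspond between samples,
which simple, lobed, and compound leaves with different numbers of lobes or
leaflets do not provide. `leaftopo` implements a persistent-homology
descriptor that compares any closed leaf outline to any other, is robust to
internal artifacts such as holes from overlapping leaflets, and supports
downstream morphospace, classification, and diversity analyses — together
with the traditional descriptors (circularity, aspect ratio, solidity) for
reference, and a parametric synthetic-leaf generator so the whole pipeline is
testable without external data.

## The descriptor

An outline is an ordered closed polygon. It is resampled to *n* = 2,000
points equally spaced by arc length, centered on its centroid, scaled so the
maximum centroid distance is 1, and rasterized as a point cloud (the traced
outline curve on a 512 × 512 grid covering [−1.1, 1.1]²). Each outline pixel
*x* gets a Gaussian density estimate over the resampled points *y₁ … yₙ*:

    Φ(x) = (1/n) Σᵢ (1/√(2π)) exp(−½ (‖x − yᵢ‖ / h)²),    h = 0.02

so pixel density is high in sinuses of lobes and serrations and at leaflet
attachment points. Sixteen annulus ("bump") kernels centered on the centroid,

    K(x) = exp(−(d(x, y) − r)² / (2σ²)),    r = i/16, σ = 1/32, i = 1 … 16,

isolate the part of the shape in each distance band; each localized density
K·Φ is swept by a threshold plane from its maximum down to its minimum, and
at 500 evenly spaced levels the Euler characteristic of the superlevel set
(number of 8-connected components minus number of 4-connected holes) is
recorded. Concatenating the 16 curves gives an 8,000-value descriptor per
leaf. PCA of the descriptor matrix defines the morphospace; linear
discriminant analysis with leave-one-out cross-validation (equal class
priors) classifies leaves into families, with significance from a
label-permutation null; per-family variance ranks across components, their
median, and the residuals of −median rank against log₁₀(count) estimate
family shape diversity corrected for sample size.

Raster convention: matrix row = y, column = x, 1-based at the R level;
pixel (i, j) has center `origin + (j − ½, i − ½) · pixel_size`.

## Worked example

```r
library(leaftopo)

# simulate a small labelled dataset: four leaf architectures, 10 leaves each
ds <- generate_dataset(leaf_presets("four-class"), n_per_class = 10, seed = 7)

# one leaf: traditional descriptors and the topological descriptor
leaf <- ds$contours[["lobed_001"]]
print(leaf)
#> <leaf_contour> id: lobed_001 (lobed) - 720 points
print(shape_descriptors(leaf), digits = 3)
#>          id circularity aspect_ratio solidity inv_aspect_ratio solidity8
#> 1 lobed_001       0.284         1.07    0.636            0.939    0.0267
length(ph_descriptor(leaf, ph_params()))
#> [1] 8000

# morphospace, family classification, and a permutation null
ph <- describe_ph(ds$contours, ph_params())
space <- fit_pca(ph)
k <- select_components(space, 0.95)          # 4 components reach 95% variance
scores <- space$scores[, 1:k]
lda_loo(scores, ds$manifest$family)
#> <leaf_classification> 40 samples, 4 classes; accuracy 1.000
permutation_test(scores, ds$manifest$family, B = 199, seed = 7)
#> <leaf_permutation> observed accuracy 1.000 vs 199 label permutations; p = 0.005
descriptor_pc_correlation(scores, describe_classic(ds$contours)$circularity)[1:3]
#> PC1 -0.47  PC2 -0.72  PC3 -0.74
```

The five-lobed leaf has low circularity (deep sinuses lengthen the
perimeter), near-1 aspect ratio (it is round overall), and reduced solidity
(lobes leave the convex hull partly empty). The four architectures are
linearly separable in the topological morphospace: every leaf is correctly
reassigned by leave-one-out LDA, and no label permutation reaches the
observed accuracy, so the add-one p-value is its minimum, 1/(B + 1).
Spearman correlations between circularity and the leading components show
the morphospace capturing traditional shape attributes in combination.

A thin command-line front end over the same functions is installed at
`system.file("cli", "leaftopo", package = "leaftopo")`, with subcommands
`simulate`, `describe-classic`, `describe-ph`, `morphospace`, `classify`,
`diversity`, and `run` (one-shot pipeline with a config hash stamped into
every output).

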