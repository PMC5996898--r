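test_that("Gaussian density matches hand-evaluated kernel values", {
  # single data point: value at the point itself, and at distance h
  expect_equal(density_at(c(0, 0), c(0, 0), h = 0.1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(density_at(c(0.1, 0), c(0, 0), h = 0.1),
               exp(-0.5) / sqrt(2 * pi), tolerance = 1e-12)
  # duplicated data points average to the same value
  expect_equal(density_at(c(0, 0), rbind(c(0, 0), c(0, 0)), h = 0.1),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_error(density_at(c(0, 0), c(0, 0), h = 0), "h must be")
})

test_that("density over a raster is positive, bounded, and kernel-consistent", {
  n <- normalize_contour(star_contour(5, 0.4), 800)
  m <- rasterize_contour(n, 128)
  f <- gaussian_density(m, n$points, h = 0.05)
  expect_true(all(f$pixels$value > 0))
  expect_true(all(f$pixels$value <= 1 / sqrt(2 * pi) + 1e-12))
  # matches direct evaluation at pixel centers
  direct <- density_at(cbind(f$pixels$x, f$pixels$y), n$points, 0.05)
  expect_equal(f$pixels$value, direct, tolerance = 1e-12)
})

test_that("annulus layout and kernel follow the ring definition", {
  ann <- make_annuli(16)
  expect_equal(ann$radius, (1:16) / 16)
  expect_equal(unique(ann$sigma), 1 / 32)
  expect_equal(ann$index, 1:16)
  expect_equal(nrow(make_annuli(1)), 1)
  expect_equal(make_annuli(1)$radius, 1)
  a <- ann[3, ]
  r <- a$radius; s <- a$sigma
  expect_equal(annulus_weight(a, c(r, 0)), 1, tolerance = 1e-12)
  expect_equal(annulus_weight(a, c(r + s, 0)), exp(-0.5), tolerance = 1e-12)
  expect_lt(annulus_weight(a, c(r + 10 * s, 0)), 1e-21)
})

test_that("localization multiplies pointwise and has an identity limit", {
  n <- normalize_contour(circle_contour(200), 400)
  m <- rasterize_contour(n, 64)
  f <- gaussian_density(m, n$points, h = 0.05)
  wide <- localized_density(f, list(radius = 0.5, sigma = 1e6,
                                    center_x = 0, center_y = 0))
  expect_equal(wide$pixels$value, f$pixels$value, tolerance = 1e-9)
  # ring far away from all pixels kills the field
  far <- localized_density(f, list(radius = 50, sigma = 0.03,
                                   center_x = 0, center_y = 0))
  expect_true(all(far$pixels$value < 1e-12))
  # a pixel on the ring keeps its density exactly
  ring <- localized_density(f, list(radius = sqrt(f$pixels$x[1]^2 + f$pixels$y[1]^2),
                                    sigma = 0.03, center_x = 0, center_y = 0))
  expect_equal(ring$pixels$value[1], f$pixels$value[1], tolerance = 1e-12)
})

test_that("Euler characteristic counts components minus holes", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  expect_identical(euler_characteristic(m), 1L)
  m2 <- m; m2[1, 7:8] <- TRUE            # second component (corner block)
  expect_identical(euler_characteristic(m2), 2L)
  m3 <- m; m3[4, 4] <- FALSE             # punch a hole
  expect_identical(euler_characteristic(m3), 0L)
  # background touching the border is not a hole
  m4 <- matrix(TRUE, 5, 5); m4[1, 3] <- FALSE
  expect_identical(euler_characteristic(m4), 1L)
})

test_that("flood fill agrees exactly with the cubical-complex oracle", {
  set.seed(11)
  for (k in 1:200) {
    m <- matrix(stats::rbinom(256, 1, runif(1, 0.15, 0.85)), 16, 16) > 0
    expect_identical(euler_characteristic(m), as.integer(ec_cubical_oracle(m)))
  }
})

test_that("superlevel EC curves match per-threshold flood fill labeling", {
  set.seed(3)
  for (rep in 1:5) {
    vals <- matrix(NA_real_, 20, 20)
    idx <- sample(400, 150)
    vals[idx] <- runif(150)
    f <- fake_density(vals)
    curve <- superlevel_ec_curve(f, 40)
    expect_length(curve$values, 40)
    expect_equal(curve$thresholds[1], max(vals, na.rm = TRUE))
    expect_equal(curve$thresholds[40], min(vals, na.rm = TRUE))
    for (j in c(1, 7, 20, 33, 40)) {
      mask <- !is.na(vals) & vals >= curve$thresholds[j]
      expect_identical(curve$values[j], euler_characteristic(mask))
    }
  }
})

test_that("two-bump fields transition from one to two components", {
  vals <- matrix(NA_real_, 10, 20)
  vals[5, 2:5] <- c(0.8, 1.0, 0.9, 0.7)     # bump peaking at 1.0
  vals[5, 14:17] <- c(0.3, 0.5, 0.4, 0.2)   # bump peaking at 0.5
  curve <- superlevel_ec_curve(fake_density(vals), 100)
  expect_identical(curve$values[1], 1L)
  expect_identical(curve$values[100], 2L)
  expect_identical(sort(unique(curve$values)), c(1L, 2L))
  expect_true(all(curve$values[curve$thresholds <= 0.5] == 2L))
})

test_that("degenerate fields follow the constant and empty-support rules", {
  vals <- matrix(NA_real_, 6, 6); vals[2:3, 2:4] <- 0.7
  curve <- superlevel_ec_curve(fake_density(vals), 10)
  expect_true(all(curve$values == 1L))
  # all-zero field: empty positive support
  zvals <- matrix(NA_real_, 6, 6); zvals[2:3, 2:4] <- 0
  zcurve <- superlevel_ec_curve(fake_density(zvals), 10)
  expect_true(all(zcurve$values == 0L))
  expect_error(superlevel_ec_curve(fake_density(vals), 1), "n_levels")
})

test_that("descriptor has block structure and propagates parameters", {
  p <- fast_params()
  d <- ph_descriptor(star_contour(5, 0.4), p)
  expect_length(d, p$n_annuli * p$n_levels)
  expect_true(all(is.finite(d)))
  expect_identical(attr(d, "id"), "star")
  mat <- describe_ph(list(star_contour(5, 0.4), circle_contour(120)), p)
  expect_equal(dim(mat), c(2L, p$n_annuli * p$n_levels))
  expect_identical(rownames(mat), c("star", "circle"))
})

test_that("descriptors are translation invariant and field domain is supported", {
  p <- fast_params()
  base <- star_contour(5, 0.4)
  moved <- base
  moved$points <- moved$points + matrix(rep(c(5, -2), each = 720), 720, 2)
  expect_identical(ph_descriptor(base, p), ph_descriptor(moved, p))
  pf <- fast_params(domain = "field")
  df <- ph_descriptor(circle_contour(120), pf)
  expect_length(df, pf$n_annuli * pf$n_levels)
  expect_true(all(is.finite(df)))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(ph_params(h = -1), "h must be")
  expect_error(ph_params(n_levels = 1), "n_levels")
  expect_error(ph_params(resolution = 8), "resolution")
  expect_silent(ph_params())
})
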