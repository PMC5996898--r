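test_that("blade limits reproduce analytic shapes", {
  # no modulation, no stretch: a circle
  circ <- generate_blade(leaf_params())
  expect_gte(circularity(circ), 0.999)
  # stretch controls the moment aspect ratio
  expect_equal(aspect_ratio(generate_blade(leaf_params(base_aspect = 3))), 3,
               tolerance = 0.05)
  # lobes cut solidity
  expect_lt(solidity(generate_blade(leaf_params(lobe_count = 5,
                                                lobe_depth = 0.5))),
            solidity(generate_blade(leaf_params())))
  # impossible modulation depth is rejected
  expect_error(generate_blade(leaf_params(lobe_count = 3, lobe_depth = 0.85,
                                          serration_freq = 9,
                                          serration_amp = 0.19)),
               "rejected")
})

test_that("descriptor knobs are monotone across parameter sweeps", {
  sol <- vapply(c(0, 0.2, 0.4, 0.6),
                function(A) solidity(generate_blade(
                  leaf_params(lobe_count = 5, lobe_depth = A))), 0)
  expect_true(all(diff(sol) < 0))
  circ <- vapply(c(0, 0.2, 0.4, 0.6),
                 function(A) circularity(generate_blade(
                   leaf_params(lobe_count = 5, lobe_depth = A))), 0)
  expect_true(all(diff(circ) < 0))
  ar <- vapply(c(1, 1.5, 2.5, 4),
               function(b) aspect_ratio(generate_blade(
                 leaf_params(base_aspect = b))), 0)
  expect_true(all(diff(ar) > 0))
})

test_that("compound leaves trace one connected outline; holes enclose regions", {
  pal <- generate_compound(leaf_params(leaflet_count = 5))
  m <- rasterize_contour(normalize_contour(pal, 2000), 256)
  expect_identical(euler_characteristic(m), 0L)   # 1 component - 1 interior
  hole <- generate_compound(leaf_params(leaflet_count = 5, hole = TRUE))
  mh <- rasterize_contour(normalize_contour(hole, 2000), 512)
  # at least one extra enclosed background region beyond the interior
  expect_lte(euler_characteristic(mh), -1L)
  # more leaflets spread the hull faster than the area
  expect_lt(solidity(generate_compound(leaf_params(leaflet_count = 7))),
            solidity(generate_compound(leaf_params(leaflet_count = 2))))
  expect_error(generate_compound(leaf_params(leaflet_count = 1)),
               "leaflet_count >= 2")
  # pinnate arrangement with petiole
  pin <- generate_compound(leaf_params(leaflet_count = 6, petiole_length = 0.3))
  mp <- rasterize_contour(normalize_contour(pin, 2000), 256)
  expect_identical(euler_characteristic(mp), 0L)
})

test_that("datasets are labelled, validated, and byte-identical under a seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  classes <- list(entire = leaf_params(base_aspect = 2, noise_sd = 0.003),
                  lobed = leaf_params(lobe_count = 5, lobe_depth = 0.4,
                                      noise_sd = 0.003))
  ds <- generate_dataset(classes, n_per_class = 4, seed = 23, dir = dir1)
  expect_length(ds$contours, 8)
  expect_equal(nrow(ds$manifest), 8)
  expect_equal(sort(unique(ds$manifest$family)), c("entire", "lobed"))
  # every contour passes validation on re-read
  back <- read_contour_dir(dir1, read_manifest(file.path(dir1, "manifest.csv")))
  expect_length(back, 8)
  expect_identical(back[[1]]$family, ds$manifest$family[1])
  generate_dataset(classes, n_per_class = 4, seed = 23, dir = dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # a different seed changes the files
  dir3 <- withr::local_tempdir()
  generate_dataset(classes, n_per_class = 4, seed = 24, dir = dir3)
  expect_false(identical(readLines(file.path(dir1, "entire_001.txt")),
                         readLines(file.path(dir3, "entire_001.txt"))))
  expect_error(generate_dataset(classes[1], 3), "2 classes")
})

test_that("well-separated classes are perfectly classified end to end", {
  classes <- list(entire = leaf_params(base_aspect = 2, noise_sd = 0.003),
                  lobed = leaf_params(lobe_count = 7, lobe_depth = 0.5,
                                      noise_sd = 0.003))
  ds <- generate_dataset(classes, n_per_class = 10, seed = 3)
  ph <- describe_ph(ds$contours, ph_params(resolution = 160, n_resample = 600,
                                           n_annuli = 8, n_levels = 60))
  space <- fit_pca(ph)
  k <- select_components(space, 0.95)
  res <- lda_loo(space$scores[, seq_len(k), drop = FALSE], ds$manifest$family)
  expect_gte(res$accuracy, 0.95)
})
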