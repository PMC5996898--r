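# Localized persistent-homology shape descriptor.
#
# A normalized outline is rasterized as a point cloud; a Gaussian density
# estimator over the outline pixels is multiplied by 16 concentric annulus
# kernels centered on the centroid; for each localized density the Euler
# characteristic (components minus holes) of the superlevel-set filtration is
# discretized into 500 values; the 16 curves are concatenated into one
# 8,000-value descriptor.

#' Parameters of the topological descriptor pipeline
#'
#' A single frozen parameter block so descriptor vectors are reproducible
#' across runs.
#'
#' @param h Gaussian density bandwidth, in normalized contour units where the
#'   maximum centroid distance is 1 (default 0.02, about two pixel widths at
#'   resolution 512).
#' @param resolution Raster grid side in pixels (default 512).
#' @param n_resample Number of equally spaced outline points (default 2000).
#' @param n_annuli Number of annulus kernels (default 16).
#' @param n_levels Number of filtration thresholds per annulus (default 500).
#' @param sigma Annulus kernel width; default `1/(2 * n_annuli)`, half the
#'   radius spacing, giving full coverage with moderate overlap.
#' @param domain Filtration domain: `"contour"` (default) filters the density
#'   restricted to the outline pixels (the point-cloud reading), `"field"`
#'   filters the smooth density over the whole grid.
#' @return Validated list of class `ph_params`.
#' @export
ph_params <- function(h = 0.02, resolution = 512L, n_resample = 2000L,
                      n_annuli = 16L, n_levels = 500L, sigma = NULL,
                      domain = c("contour", "field")) {
  domain <- match.arg(domain)
  p <- list(h = h, resolution = as.integer(resolution),
            n_resample = as.integer(n_resample),
            n_annuli = as.integer(n_annuli), n_levels = as.integer(n_levels),
            sigma = if (is.null(sigma)) 1 / (2 * n_annuli) else sigma,
            domain = domain)
  problems <- validate_params(p)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  class(p) <- "ph_params"
  p
}

validate_params <- function(p) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(p$h) && p$h > 0, "h must be > 0")
  chk(p$resolution >= 16L, "resolution must be >= 16")
  chk(p$n_resample >= 3L, "n_resample must be >= 3")
  chk(p$n_annuli >= 1L, "n_annuli must be >= 1")
  chk(p$n_levels >= 2L, "n_levels must be >= 2")
  chk(is.numeric(p$sigma) && p$sigma > 0, "sigma must be > 0")
  chk(p$domain %in% c("contour", "field"), "domain must be 'contour' or 'field'")
  problems
}

#' Gaussian density estimator over raster pixels
#'
#' For each foreground pixel center x, the estimator is the average over the
#' n outline points y_i of `(1/sqrt(2*pi)) * exp(-(|x - y_i|/h)^2 / 2)`.  The
#' kernel constant is `1/sqrt(2*pi)` with no bandwidth factor in the
#' normalizer, so values are bounded above by `1/sqrt(2*pi)`.
#'
#' @param mask A `leaf_raster` from [rasterize_contour()].
#' @param contour_points The n resampled outline points (two-column matrix or
#'   [leaf_contour()]).
#' @param h Bandwidth, > 0.
#' @param all_pixels Evaluate on every grid pixel rather than only foreground
#'   (used by the `"field"` filtration domain).
#' @return Object of class `leaf_density`: list with `pixels` (data frame
#'   `row`, `col`, `x`, `y`, `value`), `h`, and grid metadata.
#' @export
gaussian_density <- function(mask, contour_points, h, all_pixels = FALSE) {
  if (!is.numeric(h) || h <= 0) stop("bandwidth h must be > 0")
  pts <- if (inherits(contour_points, "leaf_contour"))
    contour_points$points else as.matrix(contour_points)
  if (all_pixels) {
    res <- nrow(mask$grid)
    ctr <- mask$origin[1] + (seq_len(res) - 0.5) * mask$pixel_size
    px <- expand.grid(row = seq_len(res), col = seq_len(res))
    px$x <- ctr[px$col]; px$y <- ctr[px$row]
  } else {
    px <- raster_foreground(mask)
  }
  if (nrow(px) == 0L) stop("empty raster support: no foreground pixels")
  px$value <- cpp_gaussian_density(px$x, px$y, pts[, 1], pts[, 2], h)
  structure(list(pixels = px, h = h, resolution = nrow(mask$grid),
                 origin = mask$origin, pixel_size = mask$pixel_size),
            class = "leaf_density")
}

#' Evaluate the Gaussian density estimator at arbitrary query points
#'
#' @param at Two-column matrix (or length-2 vector) of query points.
#' @param points The outline data points y_i.
#' @param h Bandwidth, > 0.
#' @return Numeric vector of density values.
#' @export
density_at <- function(at, points, h) {
  if (!is.numeric(h) || h <= 0) stop("bandwidth h must be > 0")
  at <- matrix(as.numeric(at), ncol = 2)
  points <- matrix(as.numeric(points), ncol = 2)
  cpp_gaussian_density(at[, 1], at[, 2], points[, 1], points[, 2], h)
}

#' Concentric annulus kernel specifications
#'
#' Annuli are centered on the origin (the centroid of a normalized contour)
#' with radii `i/n_annuli`, i = 1..n_annuli, so the outermost ring sits at the
#' normalized maximum radius 1.
#'
#' @param n_annuli Number of annuli (default 16).
#' @param sigma Ring width; default half the radius spacing.
#' @return Data frame with columns `index`, `radius`, `sigma`, `center_x`,
#'   `center_y`.
#' @export
make_annuli <- function(n_annuli = 16L, sigma = NULL) {
  stopifnot(n_annuli >= 1L)
  if (is.null(sigma)) sigma <- 1 / (2 * n_annuli)
  stopifnot(sigma > 0)
  data.frame(index = seq_len(n_annuli),
             radius = seq_len(n_annuli) / n_annuli,
             sigma = sigma, center_x = 0, center_y = 0)
}

#' Annulus ("bump") kernel weight
#'
#' `K(x) = exp(-(d(x, y) - r)^2 / (2 * sigma^2))` where d is Euclidean
#' distance to the annulus center y, r its radius, and sigma its width; equal
#' to 1 exactly on the ring.
#'
#' @param annulus One row of [make_annuli()] (or a list with `radius`,
#'   `sigma`, `center_x`, `center_y`).
#' @param x Two-column matrix (or length-2 vector) of evaluation points.
#' @return Weights in (0, 1].
#' @export
annulus_weight <- function(annulus, x) {
  x <- matrix(as.numeric(x), ncol = 2)
  d <- sqrt((x[, 1] - annulus$center_x)^2 + (x[, 2] - annulus$center_y)^2)
  exp(-(d - annulus$radius)^2 / (2 * annulus$sigma^2))
}

#' Localize a density field to one annulus
#'
#' Pointwise product of the annulus kernel with the density estimator,
#' isolating the density features intersecting the ring.
#'
#' @param f A `leaf_density`.
#' @param annulus One row of [make_annuli()].
#' @return A `leaf_density` with reweighted values.
#' @export
localized_density <- function(f, annulus) {
  stopifnot(inherits(f, "leaf_density"))
  w <- annulus_weight(annulus, cbind(f$pixels$x, f$pixels$y))
  f$pixels$value <- f$pixels$value * w
  f
}

#' Euler characteristic of a binary mask
#'
#' Number of 8-connected foreground components minus the number of holes
#' (4-connected background components not touching the grid border).  The
#' mixed connectivity convention avoids the raster Jordan-curve paradox and is
#' fixed, not configurable, so descriptors stay comparable.
#'
#' @param mask A `leaf_raster` or a logical/0-1 matrix.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  grid <- if (inherits(mask, "leaf_raster")) mask$grid else mask
  grid <- matrix(as.logical(grid), nrow(grid), ncol(grid))
  cpp_euler(grid)
}

#' Euler characteristic curve of a superlevel-set filtration
#'
#' Thresholds are `n_levels` evenly spaced values from the maximum of the
#' field down to its minimum (inclusive); entry j is the Euler characteristic
#' of the pixel set with value >= threshold j.  Successive superlevel sets are
#' nested, so the curve tracks components being born and merging, and holes
#' closing, as the plane sweeps down the density function.  The support is
#' the set of pixels with strictly positive density: a field that is zero
#' everywhere (an annulus far from every contour pixel) yields an all-zero
#' curve, and a constant positive field yields the EC of its full support at
#' every level.
#'
#' @param f A `leaf_density` (typically localized to one annulus).
#' @param n_levels Number of thresholds, >= 2 (default 500).
#' @return Object of class `ec_curve`: list with integer `values` and
#'   `thresholds` (descending).
#' @export
superlevel_ec_curve <- function(f, n_levels = 500L) {
  if (n_levels < 2L) stop("n_levels must be >= 2")
  stopifnot(inherits(f, "leaf_density"))
  px <- f$pixels[f$pixels$value > 0, , drop = FALSE]  # support = positive density
  if (nrow(px) == 0L) {
    return(structure(list(values = integer(n_levels),
                          thresholds = rep(NA_real_, n_levels)),
                     class = "ec_curve"))
  }
  hi <- max(px$value); lo <- min(px$value)
  thr <- seq(hi, lo, length.out = n_levels)
  thr[n_levels] <- lo  # guard against rounding excluding the minimum
  vals <- cpp_ec_curve(as.integer(px$row - 1L), as.integer(px$col - 1L),
                       px$value, f$resolution, f$resolution, thr)
  structure(list(values = vals, thresholds = thr), class = "ec_curve")
}

#' @export
print.ec_curve <- function(x, ...) {
  cat("<ec_curve>", length(x$values), "levels, EC range [",
      min(x$values), ",", max(x$values), "]\n")
  invisible(x)
}

#' Topological shape descriptor of one leaf
#'
#' Runs the full pipeline: normalize, rasterize, Gaussian density, then for
#' each annulus the localized superlevel-set Euler characteristic curve; the
#' curves are concatenated in annulus order (innermost first, thresholds high
#' to low within each block).  With defaults this is 16 x 500 = 8,000 values.
#'
#' @param c A [leaf_contour()].
#' @param params A [ph_params()] block.
#' @return Numeric vector of length `n_annuli * n_levels` with attributes
#'   `id` and `annuli`; class `ph_descriptor`.
#' @export
ph_descriptor <- function(c, params = ph_params()) {
  stopifnot(inherits(params, "ph_params"))
  nc <- normalize_contour(c, params$n_resample)
  mask <- rasterize_contour(nc, params$resolution)
  dens <- gaussian_density(mask, nc$points, params$h,
                           all_pixels = identical(params$domain, "field"))
  annuli <- make_annuli(params$n_annuli, params$sigma)
  blocks <- lapply(seq_len(nrow(annuli)), function(i) {
    f <- localized_density(dens, annuli[i, ])
    superlevel_ec_curve(f, params$n_levels)$values
  })
  structure(as.numeric(unlist(blocks)),
            id = if (inherits(c, "leaf_contour")) c$id else "leaf",
            annuli = annuli, class = "ph_descriptor")
}

#' Topological descriptors for a batch of contours
#'
#' @param contours List of [leaf_contour()] objects.
#' @param params A [ph_params()] block.
#' @param verbose Print one progress line per leaf to stderr.
#' @return Numeric matrix, one row per leaf (row names are ids), one column
#'   per descriptor entry.
#' @export
describe_ph <- function(contours, params = ph_params(), verbose = FALSE) {
  n <- length(contours)
  out <- matrix(NA_real_, n, params$n_annuli * params$n_levels)
  rownames(out) <- vapply(contours, function(c)
    if (inherits(c, "leaf_contour")) c$id else "leaf", "")
  for (k in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    out[k, ] <- ph_descriptor(contours[[k]], params)
    if (verbose)
      message(sprintf("ph: %s (%d/%d) %.2fs", rownames(out)[k], k, n,
                      proc.time()[["elapsed"]] - t0))
  }
  colnames(out) <- paste0("a", rep(seq_len(params$n_annuli),
                                   each = params$n_levels),
                          "_t", rep(seq_len(params$n_levels),
                                    params$n_annuli))
  out
}
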