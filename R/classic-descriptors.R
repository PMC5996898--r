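# Traditional shape descriptors computed on the ordered outline polygon
# (never on the raster), so values are resolution independent and the true
# perimeter of the traced outline is used.

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(pts) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

# Second-order area moments of the filled polygon, about its centroid.
# Closed-form Green's-theorem sums over edges; returns the covariance matrix
# of the uniform density over the polygon interior.
polygon_covariance <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  ixx <- sum(cross * (x^2 + x * xn + xn^2)) / 12      # integral of x^2
  iyy <- sum(cross * (y^2 + y * yn + yn^2)) / 12      # integral of y^2
  ixy <- sum(cross * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  m <- matrix(c(ixx / A - cx^2, ixy / A - cx * cy,
                ixy / A - cx * cy, iyy / A - cy^2), 2, 2)
  m
}

#' Circularity of a leaf outline
#'
#' `4 * pi * area / perimeter^2` on the closed outline polygon: 1 for a
#' circle (the isoperimetric bound), smaller for elongated, lobed, or
#' serrated outlines.
#'
#' @param c A [leaf_contour()] or two-column coordinate matrix.
#' @return Circularity in (0, 1].
#' @export
circularity <- function(c) {
  pts <- contour_points(c)
  A <- abs(shoelace_area(pts))
  P <- polygon_perimeter(pts)
  if (A <= 0 || P <= 0) stop("degenerate shape: zero area or perimeter")
  4 * pi * A / P^2
}

#' Aspect ratio of a leaf outline
#'
#' Major/minor axis ratio of the ellipse with the same second-order area
#' moments as the filled polygon (the moment-based fit used by common image
#' analysis tools).  Always >= 1.
#'
#' @param c A [leaf_contour()] or two-column coordinate matrix.
#' @return Aspect ratio >= 1; `Inf` with a warning when the minor axis is
#'   degenerate.
#' @export
aspect_ratio <- function(c) {
  pts <- contour_points(c)
  ev <- eigen(polygon_covariance(pts), symmetric = TRUE)$values
  if (ev[2] <= max(ev[1], 1) * 1e-12) {
    warning("degenerate shape: minor axis is numerically zero")
    return(Inf)
  }
  sqrt(ev[1] / ev[2])
}

#' Solidity of a leaf outline
#'
#' Filled polygon area divided by the area of its convex hull; 1 for convex
#' shapes, lower for lobed or compound outlines and long petioles.
#'
#' @param c A [leaf_contour()] or two-column coordinate matrix.
#' @return Solidity in (0, 1].
#' @export
solidity <- function(c) {
  pts <- contour_points(c)
  A <- abs(shoelace_area(pts))
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate convex hull")
  H <- abs(shoelace_area(hull))
  if (A <= 0 || H <= 0) stop("degenerate shape: zero area")
  min(A / H, 1)
}

#' Compute all traditional descriptors for one contour
#'
#' Returns circularity, aspect ratio, and solidity together with the display
#' transforms `1/aspect_ratio` and `solidity^8` (used to spread skewed
#' descriptor distributions).
#'
#' @param c A [leaf_contour()] or coordinate matrix.
#' @return One-row data frame with columns `id`, `circularity`,
#'   `aspect_ratio`, `solidity`, `inv_aspect_ratio`, `solidity8`.
#' @export
shape_descriptors <- function(c) {
  id <- if (inherits(c, "leaf_contour")) c$id else "leaf"
  d <- data.frame(id = id,
                  circularity = circularity(c),
                  aspect_ratio = aspect_ratio(c),
                  solidity = solidity(c),
                  stringsAsFactors = FALSE)
  transform_descriptors(d)
}

#' Fill in the display transforms of a descriptor table
#'
#' @param d Data frame with columns `aspect_ratio` and `solidity`.
#' @return `d` with `inv_aspect_ratio = 1/aspect_ratio` and
#'   `solidity8 = solidity^8` added or overwritten.
#' @export
transform_descriptors <- function(d) {
  stopifnot(all(c("aspect_ratio", "solidity") %in% names(d)))
  d$inv_aspect_ratio <- 1 / d$aspect_ratio
  d$solidity8 <- d$solidity^8
  d
}

#' Traditional descriptors for a batch of contours
#'
#' @param contours List of [leaf_contour()] objects.
#' @return Data frame, one row per contour.
#' @export
describe_classic <- function(contours) {
  do.call(rbind, lapply(contours, shape_descriptors))
}
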