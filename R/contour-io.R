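#' Leaf contour object
#'
#' A leaf outline as an ordered, closed planar polygon.  The last point is
#' implicitly connected back to the first; points are stored in file order and
#' never reordered on construction.
#'
#' @param points Two-column numeric matrix of (x, y) vertex coordinates, at
#'   least 3 rows, all finite.
#' @param id Sample identifier string.
#' @param family Optional taxon label.
#' @return An object of class `leaf_contour` with elements `points`, `id`,
#'   `family`.
#' @export
leaf_contour <- function(points, id = "leaf", family = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour points must have exactly two columns (x, y)")
  storage.mode(points) <- "double"
  if (nrow(points) < 3L)
    stop("a contour needs at least 3 points, got ", nrow(points))
  if (!all(is.finite(points)))
    stop("contour coordinates must all be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, id = as.character(id), family = family),
            class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat("<leaf_contour> id:", x$id,
      if (!is.null(x$family)) paste0("(", x$family, ")"),
      "-", nrow(x$points), "points\n")
  invisible(x)
}

contour_points <- function(c) {
  if (inherits(c, "leaf_contour")) c$points else leaf_contour(c)$points
}

#' Read a leaf contour from a plain-text coordinate file
#'
#' Each non-empty line holds the x and y coordinate of one outline vertex,
#' separated by whitespace or a comma (auto-detected per file).  Vertices are
#' kept in file order and treated as a closed polygon.
#'
#' @param path Path to the text file.
#' @param id Sample identifier; defaults to the file name without extension.
#' @param family Optional taxon label to attach.
#' @return A [leaf_contour()].
#' @export
read_contour_file <- function(path, id = NULL, family = NULL) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("contour file is empty: ", path)
  pts <- matrix(NA_real_, length(keep), 2L)
  for (k in seq_along(keep)) {
    ln <- trimws(lines[keep[k]])
    fields <- strsplit(ln, if (grepl(",", ln, fixed = TRUE)) "[,[:space:]]+" else "[[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals))
      stop("malformed contour line ", keep[k], " in ", path, ": '", ln, "'")
    pts[k, ] <- vals
  }
  if (nrow(pts) < 3L)
    stop("contour in ", path, " has fewer than 3 points")
  leaf_contour(pts, id = id, family = family)
}

#' Write a contour to the two-column text format
#'
#' @param contour A [leaf_contour()] or two-column matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contour_file <- function(contour, path) {
  pts <- contour_points(contour)
  writeLines(sprintf("%.10g %.10g", pts[, 1], pts[, 2]), path)
  invisible(path)
}

#' Resample, center, and scale a contour
#'
#' Resamples the closed polygon to `n_resample` points equally spaced by arc
#' length, translates so the centroid (mean of the resampled points) is at the
#' origin, and scales so the maximum distance from the origin to any point is
#' exactly 1.  Resampling is run to a fixed point (cumulative arc positions
#' equalized to within 1e-10 of the perimeter), which makes the operation
#' idempotent to high precision.
#'
#' @param c A [leaf_contour()].
#' @param n_resample Number of output vertices (default 2000).
#' @return A normalized [leaf_contour()] with `n_resample` points.
#' @export
normalize_contour <- function(c, n_resample = 2000L) {
  stopifnot(n_resample >= 3L)
  pts <- contour_points(c)
  for (iter in 1:50) {
    closed <- rbind(pts, pts[1, , drop = FALSE])
    seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
    L <- sum(seg)
    if (L <= 0)
      stop("degenerate contour: zero perimeter (all points identical)")
    cum <- c(0, cumsum(seg))
    target <- (seq_len(n_resample) - 1) * L / n_resample
    # deviation of current vertices from equal spacing (only meaningful when
    # the vertex count already equals n_resample)
    if (nrow(pts) == n_resample) {
      dev <- max(abs(cum[seq_len(n_resample)] - target))
      if (dev < 1e-10 * L) break
    }
    idx <- findInterval(target, cum, rightmost.closed = TRUE)
    idx[idx > nrow(pts)] <- nrow(pts)
    frac <- (target - cum[idx]) / pmax(seg[idx], .Machine$double.xmin)
    pts <- closed[idx, , drop = FALSE] +
      frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
  }
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  rmax <- sqrt(max(pts[, 1]^2 + pts[, 2]^2))
  if (rmax <= 0) stop("degenerate contour: zero extent")
  out <- if (inherits(c, "leaf_contour")) c else leaf_contour(pts)
  out$points <- pts / rmax
  dimnames(out$points) <- list(NULL, c("x", "y"))
  out
}

#' Rasterize a normalized contour onto a square pixel grid
#'
#' The grid covers the window `[-1.1, 1.1]^2` (a 10% margin around the unit
#' disc spanned by a normalized contour) with `resolution` pixels per side.
#' Foreground pixels are those containing a contour vertex plus all pixels
#' crossed by the polygon edges (Bresenham line tracing), so the outline is a
#' connected 8-connected curve.  Matrix row corresponds to y and column to x.
#'
#' @param c A normalized [leaf_contour()] (max radius 1).
#' @param resolution Pixels per grid side, at least 16 (default 512).
#' @return An object of class `leaf_raster`: list with `grid` (logical
#'   matrix), `origin` (xy of the grid corner), `pixel_size`.
#' @export
rasterize_contour <- function(c, resolution = 512L) {
  if (resolution < 16L) stop("resolution must be at least 16")
  pts <- contour_points(c)
  lo <- -1.1; hi <- 1.1
  grid <- cpp_rasterize(pts[, 1], pts[, 2], as.integer(resolution), lo, hi)
  structure(list(grid = grid, origin = c(lo, lo),
                 pixel_size = (hi - lo) / resolution),
            class = "leaf_raster")
}

#' @export
print.leaf_raster <- function(x, ...) {
  cat("<leaf_raster>", nrow(x$grid), "x", ncol(x$grid), "pixels,",
      sum(x$grid), "foreground\n")
  invisible(x)
}

#' Pixel-center coordinates of the foreground pixels of a raster
#'
#' @param mask A `leaf_raster`.
#' @return Data frame with 1-based `row`, `col` and real `x`, `y` centers.
#' @export
raster_foreground <- function(mask) {
  stopifnot(inherits(mask, "leaf_raster"))
  idx <- which(mask$grid, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             x = mask$origin[1] + (idx[, 2] - 0.5) * mask$pixel_size,
             y = mask$origin[2] + (idx[, 1] - 0.5) * mask$pixel_size)
}

#' Read a sample manifest table
#'
#' A delimited text table (comma or tab, auto-detected) with header columns
#' `id`, `family` and optionally `group`.
#'
#' @param path Path to the manifest file.
#' @return Data frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE)
  need <- c("id", "family")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicate sample id(s) in manifest: ", paste(unique(dup), collapse = ", "))
  keep <- intersect(c("id", "family", "group"), names(tab))
  tab[, keep, drop = FALSE]
}

#' Read every contour file in a directory
#'
#' Files are matched by extension (`.txt` by default), optionally joined to a
#' manifest for family labels.  Subdirectories one level deep are searched
#' too, mirroring a directory-per-group layout.
#'
#' @param dir Directory containing contour files.
#' @param manifest Optional manifest data frame from [read_manifest()].
#' @param pattern Filename regular expression (default `"\\.txt$"`).
#' @return List of [leaf_contour()] objects, named by id.
#' @export
read_contour_dir <- function(dir, manifest = NULL, pattern = "\\.txt$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE, recursive = TRUE)
  if (length(files) == 0L) stop("no contour files matching ", pattern, " in ", dir)
  out <- lapply(files, read_contour_file)
  names(out) <- vapply(out, function(c) c$id, "")
  if (!is.null(manifest)) {
    fam <- manifest$family[match(names(out), manifest$id)]
    for (k in seq_along(out)) out[[k]]$family <- fam[k]
  }
  out
}
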