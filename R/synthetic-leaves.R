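# Parametric synthetic leaf outlines: simple/lobed/serrated blades from polar
# modulation (closed-form control of lobe count and depth gives analytic
# expectations for descriptor tests), and compound leaves as boolean unions of
# leaflet blades traced as a single closed contour.

#' Parameters of a synthetic leaf
#'
#' @param base_aspect Blade elongation (>= 1); the blade is stretched by this
#'   factor along x.
#' @param lobe_count Number of lobes k (>= 0).
#' @param lobe_depth Lobe amplitude A in `[0, 0.9)` of the polar modulation
#'   `r = 1 + A cos(k theta)`.
#' @param serration_freq Serration frequency (>= 0).
#' @param serration_amp Serration amplitude in `[0, 0.2)`.
#' @param leaflet_count Number of leaflets (1 = simple blade; >= 2 compound).
#' @param petiole_length Rachis offset before the first leaflet pair; 0 gives
#'   a palmate arrangement, > 0 pinnate.
#' @param noise_sd Additive Gaussian coordinate noise (blade units, where the
#'   unperturbed blade radius is about 1).
#' @param hole Arrange two adjacent leaflets to overlap so the traced outline
#'   encloses an extra background region (compound leaves only).
#' @param seed Integer seed for the noise stream.
#' @return Validated list of class `leaf_params`.
#' @export
leaf_params <- function(base_aspect = 1, lobe_count = 0L, lobe_depth = 0,
                        serration_freq = 0L, serration_amp = 0,
                        leaflet_count = 1L, petiole_length = 0,
                        noise_sd = 0, hole = FALSE, seed = 1L) {
  stopifnot(base_aspect >= 1, lobe_count >= 0, lobe_depth >= 0, lobe_depth < 0.9,
            serration_freq >= 0, serration_amp >= 0, serration_amp < 0.2,
            leaflet_count >= 1, petiole_length >= 0, noise_sd >= 0,
            is.logical(hole))
  structure(list(base_aspect = base_aspect, lobe_count = as.integer(lobe_count),
                 lobe_depth = lobe_depth,
                 serration_freq = as.integer(serration_freq),
                 serration_amp = serration_amp,
                 leaflet_count = as.integer(leaflet_count),
                 petiole_length = petiole_length, noise_sd = noise_sd,
                 hole = isTRUE(hole), seed = as.integer(seed)),
            class = "leaf_params")
}

# polar blade vertices, no noise: r(theta) = 1 + A cos(k theta) + s cos(f theta)
blade_outline <- function(p, n_vertices = 720L) {
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- 1 + p$lobe_depth * cos(p$lobe_count * theta) +
    p$serration_amp * cos(p$serration_freq * theta)
  if (any(r <= 0))
    stop("rejected parameters: polar radius non-positive (lobe_depth + ",
         "serration_amp too large)")
  cbind(x = p$base_aspect * r * cos(theta), y = r * sin(theta))
}

# Proper segment-crossing check over all non-adjacent segment pairs.
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  pr <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  keep <- (j - i > 1L) & !(i == 1L & j == n)   # skip adjacent segments
  i <- i[keep]; j <- j[keep]
  # bounding-box prefilter
  bb <- pmin(x1, x2)[i] <= pmax(x1, x2)[j] & pmax(x1, x2)[i] >= pmin(x1, x2)[j] &
        pmin(y1, y2)[i] <= pmax(y1, y2)[j] & pmax(y1, y2)[i] >= pmin(y1, y2)[j]
  i <- i[bb]; j <- j[bb]
  if (length(i) == 0L) return(TRUE)
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  d1 <- cross(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
  d2 <- cross(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
  d3 <- cross(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
  d4 <- cross(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

add_noise_simple <- function(pts, noise_sd, seed, what = "blade",
                             tries = 30L) {
  if (noise_sd <= 0) return(pts)
  for (try in seq_len(tries) - 1L) {
    set.seed(seed + 7919L * try)
    noisy <- pts + matrix(rnorm(length(pts), sd = noise_sd), nrow(pts), 2)
    if (is_simple_polygon(noisy)) return(noisy)
  }
  stop("could not generate a simple (non-self-intersecting) ", what,
       " after ", tries, " noise redraws; reduce noise_sd")
}

#' Generate a simple, lobed, or serrated leaf blade
#'
#' The blade is the polar curve `r(theta) = 1 + A cos(k theta) +
#' s cos(f theta)` stretched by `base_aspect` along x, sampled at 720
#' vertices, with optional additive Gaussian coordinate noise (redrawn up to
#' 10 times if it makes the polygon self-intersect).
#'
#' @param p A [leaf_params()].
#' @param id Sample identifier.
#' @return A [leaf_contour()].
#' @export
generate_blade <- function(p, id = "blade") {
  stopifnot(inherits(p, "leaf_params"))
  pts <- blade_outline(p)
  pts <- add_noise_simple(pts, p$noise_sd, p$seed)
  leaf_contour(pts, id = id)
}

# close a path list from polyclip into a vertex matrix
path_to_matrix <- function(path) cbind(x = path$x, y = path$y)

# union a list of vertex-matrix polygons with polyclip; returns list of paths
union_polygons <- function(polys) {
  U <- list(list(x = polys[[1]][, 1], y = polys[[1]][, 2]))
  for (k in seq_along(polys)[-1]) {
    B <- list(list(x = polys[[k]][, 1], y = polys[[k]][, 2]))
    U <- polyclip::polyclip(U, B, op = "union")
  }
  U
}

# intersection of two vertex-matrix polygons; list of paths (possibly empty)
intersect_polygons <- function(A, B) {
  polyclip::polyclip(list(list(x = A[, 1], y = A[, 2])),
                     list(list(x = B[, 1], y = B[, 2])), op = "intersection")
}

# equal-arc resample of a closed vertex matrix (no centering/scaling)
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  target <- (seq_len(n) - 1) * L / n
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  frac <- (target - cum[idx]) / pmax(seg[idx], .Machine$double.xmin)
  closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
}

# ellipse polygon used as a leaflet
ellipse_poly <- function(center, a, b, angle, n = 240L) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(x = center[1] + ex * cos(angle) - ey * sin(angle),
        y = center[2] + ex * sin(angle) + ey * cos(angle))
}

disk_poly <- function(center, r, n = 240L) ellipse_poly(center, r, r, 0, n)

# splice a closed loop into a path at the nearest vertex pair, producing a
# single closed (self-overlapping) traced contour
splice_loop <- function(path, loop) {
  d2 <- outer(path[, 1], loop[, 1], `-`)^2 + outer(path[, 2], loop[, 2], `-`)^2
  hit <- arrayInd(which.min(d2), dim(d2))
  i <- hit[1]; j <- hit[2]
  loop_rot <- loop[c(j:nrow(loop), seq_len(j)), , drop = FALSE]  # closes back at j
  rbind(path[seq_len(i), , drop = FALSE], loop_rot,
        path[i:nrow(path), , drop = FALSE])
}

#' Generate a compound leaf outline
#'
#' Leaflet blades (elongated ellipses) are arranged palmately around a small
#' central disk when `petiole_length = 0`, or pinnately in opposite pairs
#' along a rachis strip plus a terminal leaflet otherwise; the union outline
#' is traced as one closed contour via polygon boolean operations.  Two
#' adjacent leaflets are always crowded together; with `hole = TRUE` they
#' must overlap and the boundary loop of the overlap region (the occlusion a
#' scanner would see through) is spliced into the traced path, so the raster
#' encloses an extra background region while the outer outline is unchanged.
#'
#' @param p A [leaf_params()] with `leaflet_count >= 2` (`hole = TRUE` needs
#'   enough leaflets for the crowded pair to overlap: 5 palmate, 6 pinnate).
#' @param id Sample identifier.
#' @return A [leaf_contour()] with 720 vertices.
#' @export
generate_compound <- function(p, id = "compound") {
  stopifnot(inherits(p, "leaf_params"))
  m <- p$leaflet_count
  if (m < 2L) stop("generate_compound needs leaflet_count >= 2")
  lens_pair <- NULL
  if (p$petiole_length == 0) {
    # palmate: leaflets radiate from a central disk; leaflet 2 is crowded
    # toward leaflet 1 (overlapping when m >= 5)
    ang <- 2 * pi * (seq_len(m) - 1) / m + pi / 2
    ang[2] <- ang[1] + 0.35 * (2 * pi / m)
    leaflets <- lapply(ang, function(a)
      ellipse_poly(center = 0.58 * c(cos(a), sin(a)), a = 0.32, b = 0.13,
                   angle = a))
    polys <- c(list(disk_poly(c(0, 0), 0.28)), leaflets)
    if (p$hole) lens_pair <- list(leaflets[[2]], leaflets[[1]])
  } else {
    # pinnate: opposite leaflet pairs along a rachis strip plus a terminal
    # leaflet; the first right-hand leaflet is shifted along the rachis into
    # the next pair (overlapping when there are >= 2 pairs)
    npairs <- (m - 1L) %/% 2L
    extra <- (m - 1L) %% 2L   # odd remainder becomes one unpaired leaflet
    xs <- p$petiole_length + 0.26 * seq_len(max(npairs + extra, 1L))
    tip <- max(xs) + 0.30
    rachis <- cbind(x = c(0, tip, tip, 0), y = c(-0.025, -0.025, 0.025, 0.025))
    leaflets <- list()
    for (i in seq_len(npairs)) {
      for (s in c(1, -1)) {
        a <- s * pi / 3
        ctr <- c(xs[i] + 0.16 * cos(a), s * 0.16 * sin(pi / 3))
        if (i == 1L && s == 1 && npairs > 1L) ctr[1] <- ctr[1] + 0.16
        leaflets[[length(leaflets) + 1L]] <-
          ellipse_poly(ctr, a = 0.20, b = 0.085, angle = a)
      }
    }
    if (extra) {
      a <- pi / 3
      ctr <- c(xs[npairs + 1L] + 0.16 * cos(a), 0.16 * sin(pi / 3))
      leaflets[[length(leaflets) + 1L]] <-
        ellipse_poly(ctr, a = 0.20, b = 0.085, angle = a)
    }
    leaflets[[length(leaflets) + 1L]] <-
      ellipse_poly(c(tip + 0.14, 0), a = 0.20, b = 0.085, angle = 0)
    polys <- c(list(rachis), leaflets)
    if (p$hole) {
      if (npairs < 2L)
        stop("pinnate hole variant needs at least 2 leaflet pairs (leaflet_count >= 6)")
      lens_pair <- list(leaflets[[1]], leaflets[[3]])
    }
  }
  U <- union_polygons(polys)
  areas <- vapply(U, function(pp) abs(shoelace_area(path_to_matrix(pp))), 0)
  if (sum(areas > 0.25 * max(areas)) > 1L)
    stop("compound leaf union is disconnected; adjust parameters")
  outline <- path_to_matrix(U[[which.max(areas)]])
  if (!is.null(lens_pair)) {
    lens <- intersect_polygons(lens_pair[[1]], lens_pair[[2]])
    lens <- Filter(function(L) abs(shoelace_area(path_to_matrix(L))) > 0.002,
                   lens)
    if (length(lens) == 0L)
      stop("hole variant: crowded leaflets do not overlap at leaflet_count = ",
           m, "; use more leaflets")
    for (L in lens) outline <- splice_loop(outline, path_to_matrix(L))
  }
  outline <- resample_closed(outline, 720L)
  if (is.null(lens_pair)) {
    outline <- add_noise_simple(outline, p$noise_sd, p$seed, "compound outline",
                                tries = 10L)
  } else if (p$noise_sd > 0) {
    set.seed(p$seed)
    outline <- outline + matrix(rnorm(length(outline), sd = p$noise_sd),
                                nrow(outline), 2)
  }
  leaf_contour(outline, id = id)
}

#' Generate one leaf from parameters
#'
#' Dispatches to [generate_blade()] or [generate_compound()] on
#' `leaflet_count`.
#'
#' @param p A [leaf_params()].
#' @param id Sample identifier.
#' @return A [leaf_contour()].
#' @export
generate_leaf <- function(p, id = "leaf") {
  if (p$leaflet_count >= 2L) generate_compound(p, id) else generate_blade(p, id)
}

#' Built-in class presets
#'
#' `"four-class"` holds four well-separated leaf architectures (entire
#' elongated, 5-lobed, serrated round, 7-leaflet palmate compound) with
#' sub-pixel digitization noise, used for end-to-end classification tests.
#'
#' @param name Preset name.
#' @return Named list of [leaf_params()].
#' @export
leaf_presets <- function(name = "four-class") {
  switch(name,
    "four-class" = list(
      entire   = leaf_params(base_aspect = 2, noise_sd = 0.003),
      lobed    = leaf_params(lobe_count = 5, lobe_depth = 0.45, noise_sd = 0.003),
      serrated = leaf_params(serration_freq = 24, serration_amp = 0.08,
                             noise_sd = 0.003),
      compound = leaf_params(leaflet_count = 7, noise_sd = 0.003)),
    stop("unknown preset: ", name))
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` instances per class.  Each instance uses a seed
#' derived deterministically from the master seed (`seed + instance counter`)
#' and jitters `base_aspect` (+/-10%) and `lobe_depth` (+/-15%) so instances
#' within a class vary; the class architecture (lobe count, leaflet count,
#' serration frequency) is fixed.
#'
#' @param classes Named list of [leaf_params()] (class label = name).
#' @param n_per_class Instances per class; a single count or one per class.
#' @param seed Master integer seed.
#' @param dir Optional directory: contour files (`<id>.txt`) and
#'   `manifest.csv` are written in the standard layout.
#' @return List with `contours` (list of [leaf_contour()]) and `manifest`
#'   (data frame `id`, `family`).
#' @export
generate_dataset <- function(classes, n_per_class, seed = 1L, dir = NULL) {
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("classes must be a named list")
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  contours <- list()
  ids <- character(); fams <- character()
  counter <- 0L
  for (ci in seq_along(classes)) {
    cls <- names(classes)[ci]
    for (i in seq_len(n_per_class[ci])) {
      counter <- counter + 1L
      p <- classes[[cls]]
      inst_seed <- as.integer(seed) + counter
      set.seed(inst_seed)
      p$base_aspect <- max(1, p$base_aspect * runif(1, 0.9, 1.1))
      if (p$lobe_depth > 0) p$lobe_depth <- p$lobe_depth * runif(1, 0.85, 1.15)
      if (p$serration_amp > 0)
        p$serration_amp <- min(p$serration_amp * runif(1, 0.85, 1.15), 0.199)
      p$seed <- inst_seed
      id <- sprintf("%s_%03d", cls, i)
      contours[[id]] <- generate_leaf(p, id = id)
      contours[[id]]$family <- cls
      ids <- c(ids, id); fams <- c(fams, cls)
    }
  }
  manifest <- data.frame(id = ids, family = fams, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(contours))
      write_contour_file(contours[[id]], file.path(dir, paste0(id, ".txt")))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(contours = contours, manifest = manifest)
}
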