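# Shared fixtures and independent oracles, all built in code.

# polygons
unit_square <- function() leaf_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                                       id = "square")
l_shape <- function() leaf_contour(rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1),
                                         c(1, 2), c(0, 2)), id = "L")
circle_contour <- function(n = 360, r = 1, center = c(0, 0), id = "circle") {
  t <- 2 * pi * (seq_len(n) - 1) / n
  leaf_contour(cbind(center[1] + r * cos(t), center[2] + r * sin(t)), id = id)
}
ellipse_contour <- function(a, b, n = 1000) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  leaf_contour(cbind(a * cos(t), b * sin(t)), id = "ellipse")
}
star_contour <- function(k = 5, A = 0.5, n = 720) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1 + A * cos(k * t)
  leaf_contour(cbind(r * cos(t), r * sin(t)), id = "star")
}

# fast parameters for pipeline-level tests where the spec pins no sizes
fast_params <- function(...) {
  ph_params(resolution = 128L, n_resample = 600L, n_annuli = 8L,
            n_levels = 60L, ...)
}

# Independent Euler characteristic oracle: local vertex/edge/face pattern
# count on the cubical complex (2x2 block contributions), vectorized; kept
# free of any package C++ code.
ec_cubical_oracle <- function(m) {
  m <- matrix(as.integer(as.logical(m)), nrow(m), ncol(m))
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  a <- p[-nrow(p), -ncol(p)]; b <- p[-nrow(p), -1]
  d <- p[-1, -ncol(p)];       e <- p[-1, -1]
  s <- a + b + d + e
  diag2 <- (s == 2L) & ((a & e) | (b & d))
  (sum(s == 1L) - sum(s == 3L) - 2L * sum(diag2)) / 4L
}

# wrap a value matrix (NA = background) as a leaf_density for curve tests
fake_density <- function(values) {
  idx <- which(!is.na(values), arr.ind = TRUE)
  structure(list(pixels = data.frame(row = idx[, 1], col = idx[, 2],
                                     x = idx[, 2] - 0.5, y = idx[, 1] - 0.5,
                                     value = values[idx]),
                 h = 1, resolution = max(dim(values)),
                 origin = c(0, 0), pixel_size = 1),
            class = "leaf_density")
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(a^2))

rotate_contour <- function(c, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  c$points <- c$points %*% t(R)
  c
}
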