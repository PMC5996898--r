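# PCA morphospace over descriptor matrices.

#' Fit a PCA morphospace
#'
#' Mean-centered (no feature scaling) principal component analysis of a
#' samples x features descriptor matrix; descriptor entries share a common
#' scale, so only centering is applied.  Components are ordered by decreasing
#' variance and each loading vector is sign-fixed so its entry of largest
#' magnitude is positive, giving reproducible signs across runs.
#'
#' @param X Numeric matrix, samples in rows (at least 2), no missing values.
#' @return Object of class `leaf_morphospace`: `scores` (samples x
#'   components), `loadings` (components x features, orthonormal rows),
#'   `explained` (variance fractions summing to 1), `feature_mean`, `sdev`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  if (!all(is.finite(X))) stop("descriptor matrix contains non-finite entries")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  rotation <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  colnames(scores) <- colnames(rotation) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 loadings = t(rotation),
                 explained = p$sdev^2 / sum(p$sdev^2),
                 feature_mean = p$center,
                 sdev = p$sdev),
            class = "leaf_morphospace")
}

#' @export
print.leaf_morphospace <- function(x, ...) {
  cat("<leaf_morphospace>", nrow(x$scores), "samples,",
      ncol(x$scores), "components; PC1 explains",
      sprintf("%.1f%%", 100 * x$explained[1]), "\n")
  invisible(x)
}

#' Number of components reaching a cumulative variance fraction
#'
#' @param m A `leaf_morphospace`.
#' @param frac Target cumulative explained-variance fraction in (0, 1]
#'   (default 0.95).
#' @return Smallest k whose first k components explain at least `frac` of the
#'   variance.
#' @export
select_components <- function(m, frac = 0.95) {
  stopifnot(inherits(m, "leaf_morphospace"))
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("frac must be in (0, 1]")
  if (frac == 1) return(sum(m$explained > 0))
  unname(which(cumsum(m$explained) >= frac - 1e-12)[1])
}

#' Rank correlations between a descriptor and PC scores
#'
#' Spearman's rho between one per-sample descriptor (e.g. circularity) and
#' each principal component's scores, used to read which traditional shape
#' attributes a topological morphospace axis captures.
#'
#' @param scores Samples x k score matrix.
#' @param d Per-sample descriptor values (same length as rows of `scores`).
#' @return Numeric vector of k Spearman correlations; `NA` with a warning for
#'   a constant descriptor.
#' @export
descriptor_pc_correlation <- function(scores, d) {
  scores <- as.matrix(scores)
  if (length(d) != nrow(scores))
    stop("descriptor length must match the number of samples")
  if (sd(d) == 0) {
    warning("constant descriptor: Spearman correlation undefined")
    return(rep(NA_real_, ncol(scores)))
  }
  apply(scores, 2, function(s) cor(d, s, method = "spearman"))
}
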