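# Family-level shape diversity: per-PC variance ranks, median rank, and
# sample-size-corrected regression residuals.

#' Per-family variance and variance ranks across components
#'
#' For each principal component, the variance of the scores of each family is
#' computed (sample variance, denominator n - 1, by default) and families are
#' ranked from most variable (rank 1) to least, with ties averaged.  Families
#' of size 1 are kept with variance 0 and a warning.
#'
#' @param scores Samples x k score matrix.
#' @param families Per-sample family labels.
#' @param population Use the population variance (denominator n) instead of
#'   the sample variance.
#' @return Object of class `leaf_diversity_table`: `count` (named integer),
#'   `variance` and `rank` (families x k matrices).
#' @export
family_variance_ranks <- function(scores, families, population = FALSE) {
  scores <- as.matrix(scores)
  families <- as.character(families)
  if (nrow(scores) != length(families))
    stop("scores and families disagree on sample count")
  fams <- sort(unique(families))
  if (length(fams) < 2L) stop("need at least 2 families")
  count <- vapply(fams, function(f) sum(families == f), 0L)
  if (any(count == 1L))
    warning("family(ies) of size 1 get variance 0: ",
            paste(fams[count == 1L], collapse = ", "))
  vmat <- matrix(0, length(fams), ncol(scores),
                 dimnames = list(fams, colnames(scores)))
  for (i in seq_along(fams)) {
    s <- scores[families == fams[i], , drop = FALSE]
    if (nrow(s) > 1L) {
      v <- apply(s, 2, var)
      if (population) v <- v * (nrow(s) - 1) / nrow(s)
      vmat[i, ] <- v
    }
  }
  rmat <- apply(vmat, 2, function(v) rank(-v, ties.method = "average"))
  structure(list(count = count, variance = vmat, rank = rmat),
            class = "leaf_diversity_table")
}

#' Median variance rank per family
#'
#' The median of a family's variance ranks across all components, a single
#' measure of overall shape diversity (low median rank = consistently among
#' the most variable families).
#'
#' @param t A `leaf_diversity_table` from [family_variance_ranks()].
#' @return Named numeric vector, one median rank per family.
#' @export
median_rank <- function(t) {
  stopifnot(inherits(t, "leaf_diversity_table"))
  apply(t$rank, 1, median)
}

#' Sample-size-corrected diversity residuals
#'
#' More abundant families tend to look more variable, so `-median_rank` is
#' regressed on `log10(count)` by ordinary least squares with intercept and
#' the residuals are returned as diversity estimates corrected for
#' representation: higher residual = more diverse than expected for the
#' family's sample count.
#'
#' @param t A `leaf_diversity_table`.
#' @return Named numeric vector of residuals (summing to 0).
#' @export
diversity_residuals <- function(t) {
  stopifnot(inherits(t, "leaf_diversity_table"))
  if (length(t$count) < 3L) stop("need at least 3 families for the regression")
  x <- log10(t$count)
  if (max(x) - min(x) < 1e-12)
    stop("all family counts are equal: regressor is singular")
  y <- -median_rank(t)
  residuals(lm(y ~ x))
}

#' Group bias test on diversity residuals
#'
#' Two-sided Wilcoxon signed-rank test that the residuals of a subset of
#' families (e.g. one phylogenetic group) are symmetric about 0, i.e. that
#' the group is neither more nor less diverse than expected.  Exact for
#' subsets of up to 25 families (zeros dropped by convention), normal
#' approximation above.
#'
#' @param residuals Named numeric vector from [diversity_residuals()].
#' @param group_members Family names of the subset to test.
#' @return The two-sided p-value.
#' @export
group_bias_test <- function(residuals, group_members) {
  r <- residuals[names(residuals) %in% group_members]
  if (length(r) == 0L) stop("no residuals found for the given group members")
  nz <- r[r != 0]
  if (length(nz) < length(r))
    warning("dropping ", length(r) - length(nz), " zero residual(s)")
  if (length(nz) == 0L) stop("empty subset after dropping zero residuals")
  unname(wilcox.test(nz, mu = 0, alternative = "two.sided",
                     exact = length(nz) <= 25L)$p.value)
}

#' Family diversity summary table
#'
#' Convenience wrapper combining [family_variance_ranks()], [median_rank()],
#' and [diversity_residuals()].
#'
#' @param scores Samples x k score matrix.
#' @param families Per-sample family labels.
#' @param population Variance denominator switch, see
#'   [family_variance_ranks()].
#' @return Data frame with columns `family`, `count`, `median_rank`,
#'   `residual`, sorted by decreasing residual.
#' @export
leaf_diversity <- function(scores, families, population = FALSE) {
  t <- family_variance_ranks(scores, families, population = population)
  med <- median_rank(t)
  res <- diversity_residuals(t)
  out <- data.frame(family = names(t$count), count = as.integer(t$count),
                    median_rank = unname(med), residual = unname(res),
                    stringsAsFactors = FALSE)
  out[order(-out$residual), ]
}
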