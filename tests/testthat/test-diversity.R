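toy_scores <- function() {
  # 3 families with planted PC1 variances 8, 2, 2 (B and C tie)
  list(scores = cbind(PC1 = c(-2, 2, -1, 1, -1, 1),
                      PC2 = c(0, 1, 0, 3, 0, 5)),
       families = rep(c("A", "B", "C"), each = 2))
}

test_that("family variances and descending average-tie ranks are correct", {
  d <- toy_scores()
  t <- family_variance_ranks(d$scores, d$families)
  expect_equal(t$variance[, "PC1"], c(A = 8, B = 2, C = 2))
  expect_equal(t$rank[, "PC1"], c(A = 1, B = 2.5, C = 2.5))
  expect_equal(unname(colSums(t$rank)), rep(6, 2))   # F(F+1)/2 per PC
  # family with identical scores gets variance 0 and last rank
  scores <- cbind(c(1, 1, 0, 2, 5, -5))
  fams <- c("flat", "flat", "v1", "v1", "v2", "v2")
  t2 <- family_variance_ranks(scores, fams)
  expect_equal(unname(t2$variance["flat", 1]), 0)
  expect_equal(unname(t2$rank["flat", 1]), 3)
  expect_error(family_variance_ranks(cbind(1:4), rep("A", 4)), "2 families")
})

test_that("ranks agree with an independent sort-based oracle", {
  set.seed(31)
  scores <- matrix(rnorm(60 * 4), 60, 4)
  fams <- sample(LETTERS[1:6], 60, replace = TRUE)
  t <- family_variance_ranks(scores, fams)
  for (j in 1:4) {
    v <- t$variance[, j]
    oracle <- vapply(v, function(vi)
      sum(v > vi) + (1 + sum(v == vi)) / 2, 0)   # average rank, descending
    expect_equal(t$rank[, j], oracle)
  }
})

test_that("median rank summarizes across components", {
  t <- structure(list(rank = rbind(A = c(2, 3, 1), B = c(1, 1, 1))),
                 class = "leaf_diversity_table")
  expect_equal(median_rank(t), c(A = 2, B = 1))
  t2 <- structure(list(rank = rbind(A = 1:4, B = 4:1)),
                  class = "leaf_diversity_table")
  expect_equal(median_rank(t2), c(A = 2.5, B = 2.5))
})

test_that("diversity residuals come from OLS of -median rank on log10 count", {
  # closed-form OLS check: counts 10^1..10^4, y = -median ranks
  t <- structure(list(count = c(a = 10L, b = 100L, c = 1000L, d = 10000L),
                      rank = rbind(a = 4, b = 3, c = 2, d = 0.5)),
                 class = "leaf_diversity_table")
  x <- 1:4; y <- c(-4, -3, -2, -0.5)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  res <- diversity_residuals(t)
  expect_equal(unname(res), y - (alpha + beta * x), tolerance = 1e-12)
  expect_equal(sum(res), 0, tolerance = 1e-9)
  # exact linear relation gives all-zero residuals
  t2 <- structure(list(count = c(a = 10L, b = 100L, c = 1000L),
                       rank = rbind(a = 3, b = 2, c = 1)),
                  class = "leaf_diversity_table")
  expect_equal(unname(diversity_residuals(t2)), rep(0, 3), tolerance = 1e-9)
  t3 <- structure(list(count = c(a = 5L, b = 5L, c = 5L),
                       rank = rbind(a = 1, b = 2, c = 3)),
                  class = "leaf_diversity_table")
  expect_error(diversity_residuals(t3), "singular")
})

test_that("group bias test gives exact signed-rank p-values", {
  r <- c(f1 = 0.3, f2 = 0.1, f3 = 0.5, f4 = 0.2, f5 = 0.9, f6 = 0.4)
  expect_equal(group_bias_test(r, names(r)), 2 / 64, tolerance = 1e-12)
  expect_equal(suppressWarnings(group_bias_test(c(a = 1, b = -1),
                                                c("a", "b"))), 1)
  expect_equal(group_bias_test(c(a = 0.7), "a"), 1)
  expect_warning(p <- group_bias_test(c(a = 0, b = 0.2, c = 0.4),
                                      c("a", "b", "c")), "zero")
  expect_equal(p, 0.5)
  expect_error(group_bias_test(c(a = 1), "zzz"), "no residuals")
})

test_that("diversity is invariant to per-PC shifts and count doubling", {
  set.seed(41)
  scores <- matrix(rnorm(40 * 3), 40, 3)
  fams <- sample(c("A", "B", "C", "D"), 40, replace = TRUE)
  t1 <- family_variance_ranks(scores, fams)
  shifted <- sweep(scores, 2, c(100, -7, 3), `+`)
  t2 <- family_variance_ranks(shifted, fams)
  expect_equal(t2$variance, t1$variance)
  expect_equal(t2$rank, t1$rank)
  expect_equal(diversity_residuals(t2), diversity_residuals(t1))
  # duplicating every sample doubles counts but (population) variances and
  # residuals are unchanged
  tp1 <- family_variance_ranks(scores, fams, population = TRUE)
  tp2 <- family_variance_ranks(rbind(scores, scores), c(fams, fams),
                               population = TRUE)
  expect_equal(tp2$variance, tp1$variance, tolerance = 1e-12)
  expect_equal(diversity_residuals(tp2), diversity_residuals(tp1),
               tolerance = 1e-9)
})

test_that("the summary table combines counts, ranks, and residuals", {
  set.seed(77)
  scores <- cbind(rnorm(18), rnorm(18))
  families <- rep(c("A", "B", "C"), c(4, 6, 8))
  tab <- leaf_diversity(scores, families)
  expect_named(tab, c("family", "count", "median_rank", "residual"))
  expect_equal(sort(tab$family), c("A", "B", "C"))
  expect_equal(tab$count[order(tab$family)], c(4L, 6L, 8L))
  expect_equal(sum(tab$residual), 0, tolerance = 1e-9)
})
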