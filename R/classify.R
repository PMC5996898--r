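# Family classification: LDA with leave-one-out cross-validation (equal class
# priors) and a label-permutation significance test.

#' LDA family classification with leave-one-out cross-validation
#'
#' Each sample is predicted by a linear discriminant model trained on all
#' remaining samples (jackknifed cross-validation, `MASS::lda(CV = TRUE)`)
#' with priors set equal across classes.  Classes with a single sample are
#' dropped with a warning (they could never be predicted from a model trained
#' without their only example).
#'
#' @param scores Samples x k numeric matrix (e.g. morphospace PC scores).
#' @param labels Per-sample class labels.
#' @return Object of class `leaf_classification`: `predicted`, `actual`,
#'   `confusion` (actual x predicted, rows normalized to sum to 1),
#'   `accuracy`, `dropped` (labels of excluded singleton classes).
#' @export
lda_loo <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels))
    stop("scores and labels disagree on sample count")
  if (ncol(scores) < 1L) stop("need at least one feature column")
  tab <- table(labels)
  dropped <- names(tab)[tab < 2L]
  if (length(dropped) == length(tab))
    stop("every class has a single sample; nothing can be cross-validated")
  if (length(dropped)) {
    warning("dropping singleton class(es): ", paste(dropped, collapse = ", "))
    keep <- !(labels %in% dropped)
    scores <- scores[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  fac <- factor(labels)
  g <- nlevels(fac)
  fit <- tryCatch(
    suppressWarnings(MASS::lda(scores, grouping = fac, CV = TRUE,
                               prior = rep(1 / g, g))),
    error = function(e)
      stop("LDA failed (", conditionMessage(e),
           "); the within-class covariance is likely singular - ",
           "use fewer components", call. = FALSE))
  predicted <- as.character(fit$class)
  actual <- as.character(fac)
  conf <- table(actual = factor(actual, levels(fac)),
                predicted = factor(predicted, levels(fac)))
  conf <- sweep(unclass(conf), 1, pmax(rowSums(conf), 1), `/`)
  structure(list(predicted = predicted, actual = actual, confusion = conf,
                 accuracy = mean(predicted == actual), dropped = dropped),
            class = "leaf_classification")
}

#' @export
print.leaf_classification <- function(x, ...) {
  cat("<leaf_classification>", length(x$actual), "samples,",
      nrow(x$confusion), "classes; accuracy",
      sprintf("%.3f", x$accuracy), "\n")
  invisible(x)
}

#' Label-permutation significance test for classification accuracy
#'
#' Builds the chance distribution of the leave-one-out accuracy by permuting
#' class labels against the shape data B times and re-running [lda_loo()].
#' The p-value uses the add-one estimator `(1 + #(null >= observed)) / (B + 1)`,
#' so it is never exactly zero.
#'
#' @param scores Samples x k numeric matrix.
#' @param labels Per-sample class labels.
#' @param B Number of permutations, >= 1 (default 1000).
#' @param seed Integer seed controlling the permutation stream.
#' @return List of class `leaf_permutation`: `observed`, `null_accuracies`
#'   (length B), `p_value`, `seed`.
#' @export
permutation_test <- function(scores, labels, B = 1000L, seed = 1L) {
  if (B < 1L) stop("B must be at least 1")
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  observed <- lda_loo(scores, labels)$accuracy
  null_acc <- numeric(B)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- sample(labels)
    null_acc[b] <- suppressWarnings(lda_loo(scores, perm)$accuracy)
  }
  structure(list(observed = observed, null_accuracies = null_acc,
                 p_value = (1 + sum(null_acc >= observed)) / (B + 1),
                 seed = seed),
            class = "leaf_permutation")
}

#' @export
print.leaf_permutation <- function(x, ...) {
  cat("<leaf_permutation> observed accuracy",
      sprintf("%.3f", x$observed), "vs", length(x$null_accuracies),
      "label permutations; p =", format(x$p_value), "\n")
  invisible(x)
}
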