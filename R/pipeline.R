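# One-shot reproducible pipeline: describe -> morphospace -> classify /
# diversity, with a validated config serialized alongside the outputs.

#' Build a pipeline run configuration
#'
#' @param contour_dir Directory of contour files.
#' @param manifest Path to the manifest CSV (`id`, `family`).
#' @param out_dir Output directory.
#' @param params A [ph_params()] block for the descriptor stage.
#' @param pcs Cumulative explained-variance fraction for component selection
#'   (default 0.95).
#' @param permutations Label permutations for the significance test
#'   (default 1000; 0 skips the test).
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(contour_dir, manifest, out_dir, params = ph_params(),
                       pcs = 0.95, permutations = 1000L, seed = 1L) {
  cfg <- list(contour_dir = contour_dir, manifest = manifest,
              out_dir = out_dir, params = params, pcs = pcs,
              permutations = as.integer(permutations), seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @return Character vector of problems; empty when every parameter is in
#'   range.
#' @export
validate_config <- function(config) {
  problems <- validate_params(config$params)
  if (!is.numeric(config$pcs) || config$pcs <= 0 || config$pcs > 1)
    problems <- c(problems, "pcs must be in (0, 1]")
  if (config$permutations < 0)
    problems <- c(problems, "permutations must be >= 0")
  if (!is.numeric(config$seed)) problems <- c(problems, "seed must be numeric")
  problems
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                              auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] start", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' Reads contours and manifest, computes traditional and topological
#' descriptors, fits the PCA morphospace, classifies family by
#' leave-one-out LDA with a permutation null, and estimates family diversity.
#' Writes `classic.csv`, `ph.csv`, `scores.csv`, `explained.csv`,
#' `confusion.csv`, `diversity.csv`, and `summary.json` (which embeds the
#' resolved config, its hash, and the package version) to `out_dir`.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_full <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config: ", paste(problems, collapse = "; "))
  if (!file.exists(config$manifest))
    stop("manifest not found: ", config$manifest)
  if (!dir.exists(config$contour_dir))
    stop("contour directory not found: ", config$contour_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  out <- function(f) file.path(config$out_dir, f)

  manifest <- stage("read", read_manifest(config$manifest))
  contours <- stage("read", read_contour_dir(config$contour_dir, manifest))

  classic <- stage("describe-classic", describe_classic(contours))
  write.csv(cbind(classic, config_hash = hash), out("classic.csv"),
            row.names = FALSE)

  ph <- stage("describe-ph", describe_ph(contours, config$params))
  utils::write.csv(data.frame(id = rownames(ph), ph, check.names = FALSE,
                              config_hash = hash),
                   out("ph.csv"), row.names = FALSE)

  space <- stage("morphospace", fit_pca(ph))
  k <- select_components(space, config$pcs)
  write.csv(data.frame(id = rownames(ph),
                       space$scores[, seq_len(k), drop = FALSE],
                       config_hash = hash),
            out("scores.csv"), row.names = FALSE)
  write.csv(data.frame(component = seq_along(space$explained),
                       explained = space$explained, config_hash = hash),
            out("explained.csv"), row.names = FALSE)

  fam <- manifest$family[match(rownames(ph), manifest$id)]
  scores_k <- space$scores[, seq_len(k), drop = FALSE]
  cls <- stage("classify", lda_loo(scores_k, fam))
  write.csv(cbind(as.data.frame(cls$confusion), config_hash = hash),
            out("confusion.csv"), row.names = TRUE)
  perm <- if (config$permutations > 0)
    stage("permutation", permutation_test(scores_k, fam,
                                          B = config$permutations,
                                          seed = config$seed))
  else NULL

  # the size correction needs unequal family counts; fall back to median
  # ranks alone when the regressor is singular (e.g. balanced simulations)
  div <- tryCatch(stage("diversity", leaf_diversity(scores_k, fam)),
                  error = function(e) {
                    warning("diversity residuals unavailable: ",
                            conditionMessage(e), call. = FALSE)
                    t <- family_variance_ranks(scores_k, fam)
                    data.frame(family = names(t$count),
                               count = as.integer(t$count),
                               median_rank = unname(median_rank(t)),
                               residual = NA_real_)
                  })
  write.csv(cbind(div, config_hash = hash), out("diversity.csv"),
            row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("leaftopo")),
    config = config[setdiff(names(config), "out_dir")],
    config_hash = hash,
    n_leaves = length(contours),
    n_components = k,
    explained_by_selected = sum(space$explained[seq_len(k)]),
    accuracy = cls$accuracy,
    permutation_p = if (!is.null(perm)) perm$p_value else NA,
    permutations = config$permutations)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE),
             out("summary.json"))
  invisible(summary)
}
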