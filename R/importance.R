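#' Permutation variable importance (out-of-bag MSE increase)
#'
#' For every tree and predictor, the predictor's column is permuted among
#' the tree's out-of-bag cases and the increase in the tree-level
#' out-of-bag MSE is recorded; a predictor's importance is the mean
#' increase over trees.  A predictor never split on in a tree contributes
#' an increase of exactly zero for that tree; negative increases are
#' reported as-is, not truncated.
#'
#' @param forest a [fit_forest()] result.
#' @param predictors column names or indices to evaluate (default all).
#' @param n_perm independent permutations averaged per tree (default 1;
#'   the tree ensemble absorbs permutation noise).
#' @param seed integer seed for the permutation streams.
#' @return an `importance_profile`: a data frame with columns `predictor`,
#'   `category`, `importance`, `se` (standard error over trees) and
#'   `rank`, with the per-tree increase matrix in
#'   `attr(, "per_tree")`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 60, seed = 2))
#' X <- as.matrix(cohort[, timing_predictors()])
#' fit <- fit_forest(X, scale_signal(cohort$gm_signal),
#'                   forest_config(n_trees = 50, seed = 2))
#' head(permutation_importance(fit))
#' @export
permutation_importance <- function(forest, predictors = NULL, n_perm = 1,
                                   seed = forest$config$seed) {
  stopifnot(inherits(forest, "cforest_fit"))
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (all(round(forest$config$subsample_fraction * nrow(forest$X)) >= nrow(forest$X)))
    stop("no out-of-bag cases; importance needs subsample_fraction < 1",
         call. = FALSE)
  p <- ncol(forest$X)
  cols <- forest$col_names
  if (is.null(predictors)) {
    sel <- seq_len(p)
  } else if (is.character(predictors)) {
    sel <- match(predictors, cols)
    if (anyNA(sel))
      stop("unknown predictors: ",
           paste(predictors[is.na(sel)], collapse = ", "), call. = FALSE)
  } else {
    sel <- as.integer(predictors)
    if (any(sel < 1 | sel > p)) stop("predictor index out of range", call. = FALSE)
  }
  per_tree <- cpp_importance(forest$trees, forest$in_bag, forest$X, forest$y,
                             sel, as.integer(n_perm), check_seed(seed))
  rownames(per_tree) <- if (is.null(cols)) paste0("V", sel) else cols[sel]
  imp <- rowMeans(per_tree)
  se <- apply(per_tree, 1, stats::sd) / sqrt(ncol(per_tree))
  categories <- predictor_categories(rownames(per_tree))
  out <- data.frame(predictor = rownames(per_tree),
                    category = categories,
                    importance = unname(imp),
                    se = unname(se),
                    rank = rank(-imp, ties.method = "min"),
                    row.names = NULL)
  attr(out, "per_tree") <- per_tree
  attr(out, "n_permutations") <- as.integer(n_perm)
  attr(out, "seed") <- seed
  class(out) <- c("importance_profile", "data.frame")
  out
}

# Categorize predictor columns by the standard cohort naming scheme;
# anything unrecognized is "control".
predictor_categories <- function(cols) {
  out <- rep("control", length(cols))
  out[grepl("^age_\\d+_\\d+$", cols)] <- "age-bin"
  out[cols %in% c("physical", "emotional", "sexual", "neglect")] <- "type"
  out[cols == "n_types"] <- "n_types"
  out[cols == "duration_years"] <- "duration"
  out[cols == "prenatal_dv"] <- "prenatal"
  out
}

#' Write an importance table as TSV
#'
#' @param profile an `importance_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_importance <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
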