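#' Configuration of a conditional inference forest
#'
#' Defaults are the conventional settings for this design: 200 unpruned
#' conditional trees with 4 candidate variables per node, each tree grown
#' on a 0.632 without-replacement subsample of the cases.
#'
#' @param n_trees number of trees.
#' @param mtry candidate predictors per node.
#' @param subsample_fraction fraction of cases drawn without replacement
#'   per tree, in (0, 1].
#' @param tree_params a [ctree_params()]; its `mtry` is overridden by
#'   `mtry`.
#' @param seed master integer seed; per-tree streams are split from it
#'   deterministically.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200, mtry = 4, subsample_fraction = 0.632,
                          tree_params = ctree_params(mtry = mtry), seed = 1L) {
  if (n_trees < 1) stop("n_trees must be at least 1", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  tree_params$mtry <- as.integer(mtry)
  structure(list(n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry),
                 subsample_fraction = subsample_fraction,
                 tree_params = tree_params,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit a conditional inference forest
#'
#' Each tree is fitted on its own without-replacement subsample with fresh
#' candidate draws at every node.  The fit is deterministic given the
#' configuration seed: per-tree random streams are split from the master
#' seed by a splitmix64 hash, so forests reproduce bit-identically across
#' platforms.
#'
#' @param X numeric predictor matrix (no missing values), n >= 4.
#' @param y numeric response.
#' @param config a [forest_config()].
#' @return an object of class `cforest_fit` with elements `trees` (node
#'   tables), `in_bag` (per-tree sorted case indices), `config`,
#'   `col_names`, and the training `X`, `y` for out-of-bag evaluation.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 40, seed = 1))
#' X <- as.matrix(cohort[, timing_predictors()])
#' fit <- fit_forest(X, scale_signal(cohort$gm_signal),
#'                   forest_config(n_trees = 25, seed = 1))
#' oob_mse(fit)
#' @export
fit_forest <- function(X, y, config = forest_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_no_missing(X, y)
  if (nrow(X) < 4) stop("need at least 4 cases to fit a forest", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  k <- round(config$subsample_fraction * nrow(X))
  if (k < config$tree_params$min_split)
    warning("subsample size ", max(k, 1),
            " is below min_split; trees will be root-only", call. = FALSE)
  tp <- config$tree_params
  fit <- cpp_fit_forest(X, as.double(y), config$n_trees, tp$mtry,
                        tp$min_split, tp$min_bucket, tp$alpha, tp$max_depth,
                        config$subsample_fraction, check_seed(config$seed))
  structure(list(trees = fit$trees, in_bag = fit$in_bag, config = config,
                 col_names = colnames(X), X = X, y = as.double(y)),
            class = "cforest_fit")
}

#' @export
print.cforest_fit <- function(x, ...) {
  cat("Conditional inference forest:", length(x$trees), "trees, mtry",
      x$config$mtry, "\n")
  cat("  n =", nrow(x$X), "cases, p =", ncol(x$X), "predictors,",
      "subsample fraction", x$config$subsample_fraction, "\n")
  invisible(x)
}

#' Forest predictions
#'
#' Aggregation is the unweighted mean of tree predictions.  With
#' `type = "oob"` (training data only) each case is predicted by the trees
#' whose subsample excluded it; a case in-bag for every tree receives
#' `NA`.
#'
#' @param object a `cforest_fit`.
#' @param newdata matrix with the training column layout; defaults to the
#'   training data.
#' @param type `"response"` (all trees) or `"oob"`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.cforest_fit <- function(object, newdata = NULL,
                                type = c("response", "oob"), ...) {
  type <- match.arg(type)
  if (type == "oob") {
    if (!is.null(newdata))
      stop("out-of-bag predictions are defined for the training data only",
           call. = FALSE)
    newdata <- object$X
  } else if (is.null(newdata)) {
    newdata <- object$X
  }
  X <- check_layout(newdata, object$col_names)
  per_tree <- cpp_predict_trees(object$trees, object$in_bag, X, ncol(X))
  if (type == "response") return(rowMeans(per_tree))
  n <- nrow(X)
  oob <- matrix(TRUE, n, length(object$trees))
  for (t in seq_along(object$in_bag)) oob[object$in_bag[[t]], t] <- FALSE
  pred <- rep(NA_real_, n)
  any_oob <- rowSums(oob) > 0
  pred[any_oob] <- rowSums(per_tree * oob)[any_oob] / rowSums(oob)[any_oob]
  pred
}

#' @rdname predict.cforest_fit
#' @param forest a `cforest_fit`.
#' @param X new data (omit for training data).
#' @param oob logical; out-of-bag mode.
#' @export
predict_forest <- function(forest, X = NULL, oob = FALSE) {
  predict.cforest_fit(forest, newdata = if (oob) NULL else X,
                      type = if (oob) "oob" else "response")
}

#' Out-of-bag mean squared error of a fitted forest
#'
#' Mean over the training cases with at least one out-of-bag prediction of
#' the squared error against the training response.
#'
#' @param forest a `cforest_fit`.
#' @return non-negative scalar.
#' @export
oob_mse <- function(forest) {
  pred <- predict.cforest_fit(forest, type = "oob")
  ok <- !is.na(pred)
  if (!any(ok))
    stop("no out-of-bag cases; use subsample_fraction < 1", call. = FALSE)
  mean((forest$y[ok] - pred[ok])^2)
}

#' Serialize a forest to a JSON bundle
#'
#' @param forest a `cforest_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
forest_to_json <- function(forest, path = NULL) {
  cfg <- forest$config
  cfg$tree_params <- unclass(cfg$tree_params)
  js <- jsonlite::toJSON(list(config = unclass(cfg),
                              columns = forest$col_names,
                              in_bag = forest$in_bag,
                              trees = forest$trees),
                         dataframe = "rows", na = "null", digits = NA,
                         auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
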