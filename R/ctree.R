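#' Hyperparameters of the conditional inference tree learner
#'
#' @param mtry number of candidate predictors drawn at each node
#'   (default 4).
#' @param min_split minimum node size at which a split is attempted.
#' @param min_bucket minimum child-node size.
#' @param alpha significance threshold for the node-level association test
#'   (Bonferroni-adjusted over the `mtry` candidates); `alpha = 1` disables
#'   stopping by the test, giving unpruned trees as used inside forests.
#' @param max_depth maximum tree depth (`Inf` for unlimited).
#' @return an object of class `ctree_params`.
#' @export
ctree_params <- function(mtry = 4, min_split = 8, min_bucket = 3,
                         alpha = 1, max_depth = Inf) {
  if (mtry < 1) stop("mtry must be at least 1", call. = FALSE)
  if (min_bucket < 1) stop("min_bucket must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  structure(list(mtry = as.integer(mtry),
                 min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket),
                 alpha = alpha,
                 max_depth = if (is.finite(max_depth))
                   as.integer(max_depth) else .Machine$integer.max),
            class = "ctree_params")
}

#' Standardized linear association statistic with asymptotic p-value
#'
#' The permutation-test statistic used for variable selection at tree
#' nodes: `T = sum x_i (y_i - mean(y))`, standardized by its exact
#' conditional moments under random permutation of the response
#' (`E[T] = 0`, `Var[T] = Sxx * Syy / (n - 1)`), with a two-sided p-value
#' from the standard normal.  A zero-variance `x` or `y` gives statistic 0
#' and p-value 1.
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return list with `statistic` (the absolute standardized score) and
#'   `p_value`.
#' @export
linear_association_statistic <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  check_no_missing(x, y)
  v <- cpp_assoc(as.double(x), as.double(y))
  list(statistic = unname(v[1]), p_value = unname(v[2]))
}

#' Select the split variable among a candidate set
#'
#' Computes the association p-value of each candidate column against the
#' response and returns the candidate with the smallest p-value; ties go
#' to the smallest column index.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param candidate_idx column indices to evaluate.
#' @return list with `chosen` (column index) and `p_values` (named by
#'   column index).
#' @export
select_split_variable <- function(X, y, candidate_idx) {
  if (!length(candidate_idx)) stop("candidate set is empty", call. = FALSE)
  X <- as.matrix(X)
  pv <- vapply(candidate_idx, function(j)
    linear_association_statistic(X[, j], y)$p_value, numeric(1))
  names(pv) <- as.character(candidate_idx)
  ord <- candidate_idx[order(pv, candidate_idx)]
  list(chosen = ord[1], p_values = pv)
}

#' Best binary split of a single predictor
#'
#' Evaluates every midpoint between consecutive distinct values of `x`
#' whose induced children both hold at least `min_bucket` cases and
#' returns the cutpoint maximizing the standardized two-sample
#' mean-difference statistic.  Ties keep the smallest threshold; cases
#' equal to the threshold are routed left (`x <= t`).
#'
#' @param x numeric predictor.
#' @param y numeric response.
#' @param min_bucket minimum child size.
#' @return list with `threshold` and `statistic`, or `NULL` when no
#'   admissible cutpoint exists.
#' @export
best_binary_split <- function(x, y, min_bucket = 1) {
  check_no_missing(x, y)
  res <- cpp_best_split(as.double(x), as.double(y), as.integer(min_bucket))
  if (!res$found) return(NULL)
  list(threshold = res$threshold, statistic = res$statistic)
}

#' Fit a single conditional inference tree
#'
#' Recursive fitting: at each node `mtry` candidate predictors are drawn,
#' the candidate with the smallest association p-value is selected, and
#' the node is split at the candidate's best cutpoint.  Growth stops when
#' the node is smaller than `min_split`, the depth limit is reached, the
#' Bonferroni-adjusted minimum p-value exceeds `alpha`, or no admissible
#' cutpoint exists.  Terminal predictions are node means.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response.
#' @param params a [ctree_params()].
#' @param seed integer seed for the candidate draws.
#' @return an object of class `sp_ctree` holding the node table.
#' @examples
#' X <- cbind(x = c(0, 0, 0, 1, 1, 1))
#' fit <- fit_ctree(X, c(1, 1, 1, 9, 9, 9),
#'                  ctree_params(mtry = 1, min_split = 2, min_bucket = 1))
#' predict(fit, X)
#' @export
fit_ctree <- function(X, y, params = ctree_params(), seed = 1L) {
  X <- as.matrix(X)
  check_no_missing(X, y)
  if (nrow(X) < 1) stop("need at least one observation", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  storage.mode(X) <- "double"
  fit <- cpp_fit_forest(X, as.double(y), 1L, params$mtry, params$min_split,
                        params$min_bucket, params$alpha, params$max_depth,
                        1.0, check_seed(seed))
  structure(list(nodes = fit$trees[[1]],
                 col_names = colnames(X),
                 params = params, seed = seed),
            class = "sp_ctree")
}

#' @export
print.sp_ctree <- function(x, ...) {
  n_term <- sum(is.na(x$nodes$split_var))
  cat("Conditional inference tree:", nrow(x$nodes), "nodes,",
      n_term, "terminal\n")
  invisible(x)
}

#' Route cases through a fitted tree
#'
#' @param object an `sp_ctree`.
#' @param newdata matrix or data frame with the training column layout.
#' @param ... unused.
#' @return numeric predictions (terminal-node means).
#' @export
predict.sp_ctree <- function(object, newdata, ...) {
  X <- check_layout(newdata, object$col_names)
  drop(cpp_predict_trees(list(object$nodes), list(integer(0)), X, ncol(X)))
}

#' @rdname predict.sp_ctree
#' @param tree an `sp_ctree`.
#' @param X new data.
#' @export
predict_tree <- function(tree, X) predict.sp_ctree(tree, X)

#' Tree depth (root = depth 0)
#'
#' @param tree an `sp_ctree`.
#' @return integer depth.
#' @export
tree_depth <- function(tree) {
  nodes <- tree$nodes
  depth_of <- function(i, d) {
    if (is.na(nodes$split_var[i])) return(d)
    max(depth_of(nodes$left[i], d + 1L), depth_of(nodes$right[i], d + 1L))
  }
  depth_of(1L, 0L)
}

#' Serialize a fitted tree to JSON
#'
#' Node records carry split-variable names, thresholds, child links and
#' terminal statistics, for inspection and text fixtures.
#'
#' @param tree an `sp_ctree`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- tree$nodes
  nodes$split_name <- ifelse(is.na(nodes$split_var), NA_character_,
                             tree$col_names[nodes$split_var])
  js <- jsonlite::toJSON(list(params = unclass(tree$params),
                              seed = tree$seed,
                              columns = tree$col_names,
                              nodes = nodes),
                         dataframe = "rows", na = "null", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

check_layout <- function(newdata, col_names) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(col_names)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(col_names))
        stop("newdata has ", ncol(X), " columns; expected ",
             length(col_names), call. = FALSE)
    } else {
      absent <- setdiff(col_names, colnames(X))
      if (length(absent))
        stop("newdata lacks columns: ", paste(absent, collapse = ", "),
             call. = FALSE)
      X <- X[, col_names, drop = FALSE]
    }
  }
  check_no_missing(X)
  X
}
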