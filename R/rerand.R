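#' Re-randomization null distribution of importance profiles
#'
#' Builds the null by breaking the association between response and
#' exposure history: the response vector is permuted across subjects B
#' times and the entire forest is refit to each permuted response, leaving
#' the (correlated) predictor matrix intact.  Each row of the result is
#' the permutation-importance profile of one refit, restricted to
#' `predictors`.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param predictors column names or indices the null is recorded for.
#' @param config a [forest_config()] used for every refit.
#' @param B number of re-randomizations (10,000 for production analyses;
#'   tests use 99-499).
#' @param seed integer seed; one stream per re-randomization is split off
#'   deterministically.
#' @param n_perm permutations per tree inside each importance evaluation.
#' @return B x length(predictors) matrix with predictor column names.
#' @export
rerandomization_null <- function(X, y, predictors = NULL,
                                 config = forest_config(), B = 199,
                                 seed = config$seed, n_perm = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_no_missing(X, y)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  cols <- colnames(X)
  if (is.null(predictors)) {
    sel <- seq_len(ncol(X))
  } else if (is.character(predictors)) {
    sel <- match(predictors, cols)
    if (anyNA(sel))
      stop("unknown predictors: ",
           paste(predictors[is.na(sel)], collapse = ", "), call. = FALSE)
  } else sel <- as.integer(predictors)
  tp <- config$tree_params
  nm <- cpp_rerand_null(X, as.double(y), sel, as.integer(B), config$n_trees,
                        tp$mtry, tp$min_split, tp$min_bucket, tp$alpha,
                        tp$max_depth, config$subsample_fraction,
                        as.integer(n_perm), check_seed(seed))
  colnames(nm) <- if (is.null(cols)) paste0("V", sel) else cols[sel]
  nm
}

# named observed-importance vector from a profile or named numeric
observed_vector <- function(observed) {
  if (inherits(observed, "importance_profile"))
    return(stats::setNames(observed$importance, observed$predictor))
  if (is.numeric(observed) && !is.null(names(observed))) return(observed)
  stop("`observed` must be an importance_profile or a named numeric vector",
       call. = FALSE)
}

#' Max-statistic re-randomization test for peak importance
#'
#' Tests whether the maximal observed importance over a predictor set
#' could have arisen by chance: the statistic is the maximum observed
#' importance over `predictors`, the null draws are the maxima over the
#' same set within each re-randomized profile, and the p-value is the
#' add-one permutation estimate `(1 + #{null >= obs}) / (B + 1)`.
#'
#' @param observed an `importance_profile` or named numeric vector.
#' @param null_matrix matrix from [rerandomization_null()] with predictor
#'   column names.
#' @param predictors subset of predictors the maximum is taken over
#'   (default: all columns of `null_matrix`).
#' @return list with `statistic`, `peak` (name of the maximizing
#'   predictor), `p_value` and `B`.
#' @export
max_importance_test <- function(observed, null_matrix, predictors = NULL) {
  obs <- observed_vector(observed)
  if (is.null(predictors)) predictors <- colnames(null_matrix)
  if (!length(predictors)) stop("predictor set is empty", call. = FALSE)
  absent <- setdiff(predictors, intersect(names(obs), colnames(null_matrix)))
  if (length(absent))
    stop("predictors absent from observed or null: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!nrow(null_matrix)) stop("null matrix is empty", call. = FALSE)
  obs_sub <- obs[predictors]
  statistic <- max(obs_sub)
  null_max <- apply(null_matrix[, predictors, drop = FALSE], 1, max)
  B <- length(null_max)
  list(statistic = statistic,
       peak = names(obs_sub)[which.max(obs_sub)],
       p_value = (1 + sum(null_max >= statistic)) / (B + 1),
       B = B)
}

#' Marginal per-predictor re-randomization p-values
#'
#' For each predictor, the add-one permutation p-value of its observed
#' importance against its own null column:
#' `p_j = (1 + #{null[, j] >= obs_j}) / (B + 1)`.
#'
#' @inheritParams max_importance_test
#' @return named p-value vector over the columns of `null_matrix`.
#' @export
per_predictor_pvalues <- function(observed, null_matrix) {
  obs <- observed_vector(observed)[colnames(null_matrix)]
  B <- nrow(null_matrix)
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(null_matrix[, j] >= obs[j])) / (B + 1), numeric(1))
  stats::setNames(p, colnames(null_matrix))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{k >= i} p_(k) * m / k`, capped
#' at 1 and mapped back to input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Combined-window re-randomization test
#'
#' Tests the summed importance of a contiguous block of age bins against
#' a selection-aware null: the statistic is the sum of observed
#' importances over `window`; each null draw is the maximum, over all
#' contiguous windows of the same length in the predictor ordering, of
#' the summed null importances, so the test accounts for having picked
#' the best-looking window.
#'
#' @param observed an `importance_profile` or named numeric vector.
#' @param null_matrix re-randomization null matrix whose column order
#'   defines adjacency (age bins in age order).
#' @param window predictor names or column indices forming a contiguous
#'   block in that order.
#' @return list with `statistic`, `window`, `p_value`, `B`.
#' @export
combined_window_test <- function(observed, null_matrix, window) {
  obs <- observed_vector(observed)
  cols <- colnames(null_matrix)
  idx <- if (is.character(window)) match(window, cols) else as.integer(window)
  if (anyNA(idx) || any(idx < 1 | idx > length(cols)))
    stop("window names/indices not found among the null predictors",
         call. = FALSE)
  idx <- sort(idx)
  if (length(idx) < 1 || !all(diff(idx) == 1L))
    stop("window must be a contiguous block of predictors", call. = FALSE)
  w <- length(idx)
  statistic <- sum(obs[cols[idx]])
  p_all <- length(cols)
  starts <- seq_len(p_all - w + 1L)
  null_best <- apply(null_matrix, 1, function(row) {
    cs <- cumsum(c(0, row))
    max(cs[starts + w] - cs[starts])
  })
  B <- length(null_best)
  list(statistic = statistic, window = cols[idx],
       p_value = (1 + sum(null_best >= statistic)) / (B + 1), B = B)
}

#' Full re-randomization significance analysis
#'
#' Convenience wrapper combining the null construction, the max-statistic
#' test, marginal per-predictor p-values and their BH-FDR correction, and
#' optionally a combined-window test.
#'
#' @param observed an `importance_profile` for the fitted forest.
#' @param X,y the data the forest was fitted to.
#' @param config the [forest_config()] to refit with.
#' @param max_over predictors the max statistic is taken over (e.g. age
#'   bins only in the timing design).
#' @param B number of re-randomizations.
#' @param seed integer seed.
#' @param window optional contiguous window for [combined_window_test()].
#' @return an object of class `rerand_result`.
#' @export
rerand_analysis <- function(observed, X, y, config = forest_config(),
                            max_over = NULL, B = 199, seed = config$seed,
                            window = NULL) {
  obs <- observed_vector(observed)
  nm <- rerandomization_null(X, y, predictors = names(obs), config = config,
                             B = B, seed = seed)
  if (is.null(max_over)) max_over <- colnames(nm)
  mx <- max_importance_test(obs, nm, max_over)
  p <- per_predictor_pvalues(obs, nm[, max_over, drop = FALSE])
  q <- bh_fdr(p)
  cmb <- if (!is.null(window))
    combined_window_test(obs, nm[, max_over, drop = FALSE], window) else NULL
  structure(list(observed = observed, max_test = mx,
                 p_per_predictor = p, q_per_predictor = q,
                 combined = cmb,
                 null_quantiles = apply(nm, 2, stats::quantile,
                                        probs = c(0.5, 0.9, 0.95, 0.99)),
                 B = B, seed = seed),
            class = "rerand_result")
}

#' @export
print.rerand_result <- function(x, ...) {
  cat("Re-randomization test (B =", x$B, ")\n")
  cat("  peak predictor:", x$max_test$peak,
      sprintf("(importance %.4g, p = %.4g)\n",
              x$max_test$statistic, x$max_test$p_value))
  sig <- names(x$q_per_predictor)[x$q_per_predictor < 0.05]
  cat("  predictors with q < 0.05:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  if (!is.null(x$combined))
    cat(sprintf("  combined window [%s]: statistic %.4g, p = %.4g\n",
                paste(x$combined$window, collapse = ", "),
                x$combined$statistic, x$combined$p_value))
  invisible(x)
}
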