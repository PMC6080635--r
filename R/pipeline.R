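#' Scale a regional signal to mean 100, SD 10
#'
#' Z-transforms with the sample mean and sample standard deviation
#' (n - 1 denominator), then maps to the conventional arbitrary scale of
#' mean 100 and SD 10 used for regional beta scores.
#'
#' @param values numeric vector, at least 2 non-identical values.
#' @return scaled vector with sample mean 100 and sample SD 10.
#' @examples
#' scale_signal(c(1, 2, 3))  # 90 100 110
#' @export
scale_signal <- function(values) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (anyNA(values)) stop("missing values are not supported", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("cannot scale a constant signal (zero SD)", call. = FALSE)
  (values - mean(values)) / s * 10 + 100
}

#' Extract the cluster eigenvariate from a voxel matrix
#'
#' Returns the first left singular vector of the column-centered
#' subjects-by-voxels matrix, scaled by its singular value: one summary
#' gray-matter value per subject, the dominant mode of within-cluster
#' volume variation.  The sign is fixed so the eigenvariate correlates
#' positively with the subject-wise mean voxel signal.
#'
#' @param voxel_matrix numeric matrix, subjects in rows, cluster voxels in
#'   columns; no missing values.
#' @return numeric vector, one value per subject.
#' @export
cluster_eigenvariate <- function(voxel_matrix) {
  M <- as.matrix(voxel_matrix)
  if (nrow(M) < 2) stop("need at least two subjects", call. = FALSE)
  if (ncol(M) < 1) stop("need at least one voxel", call. = FALSE)
  check_no_missing(M)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc, nu = 1, nv = 0)
  if (sv$d[1] <= sqrt(.Machine$double.eps))
    stop("voxel matrix is constant across subjects (rank 0 after centering)",
         call. = FALSE)
  v <- sv$u[, 1] * sv$d[1]
  ref <- rowMeans(Mc)
  s <- sum(v * ref)
  if (s < 0) v <- -v
  drop(v)
}

run_config_defaults <- function(n_trees = 200, mtry = 4,
                                subsample_fraction = 0.632, B = 199,
                                n_perm = 1, seed = 1L, window = NULL) {
  list(n_trees = n_trees, mtry = mtry,
       subsample_fraction = subsample_fraction, B = B, n_perm = n_perm,
       seed = seed, window = window)
}

require_columns <- function(cohort, cols, what) {
  absent <- setdiff(cols, names(cohort))
  if (length(absent))
    stop(what, " design columns missing from cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
}

run_design <- function(cohort, response_name, predictor_cols, max_over,
                       design, run_config) {
  rc <- do.call(run_config_defaults, run_config)
  require_columns(cohort, c(predictor_cols, response_name), design)
  X <- as.matrix(as.data.frame(cohort)[, predictor_cols, drop = FALSE])
  storage.mode(X) <- "double"
  check_no_missing(X)
  y <- scale_signal(as.data.frame(cohort)[[response_name]])
  cfg <- forest_config(n_trees = rc$n_trees, mtry = rc$mtry,
                       subsample_fraction = rc$subsample_fraction,
                       seed = rc$seed)
  fit <- fit_forest(X, y, cfg)
  imp <- permutation_importance(fit, n_perm = rc$n_perm, seed = rc$seed)
  rr <- rerand_analysis(imp, X, y, config = cfg, max_over = max_over,
                        B = rc$B, seed = rc$seed, window = rc$window)
  oob <- predict.cforest_fit(fit, type = "oob")
  ok <- !is.na(oob)
  structure(list(design = design,
                 response = response_name,
                 importance = imp,
                 rerand = rr,
                 prediction_r = stats::cor(oob[ok], y[ok]),
                 oob_mse = mean((y[ok] - oob[ok])^2),
                 run_config = rc,
                 n = nrow(X),
                 predictors = predictor_cols),
            class = "analysis_report")
}

#' Timing (sensitive-period) analysis
#'
#' Fits the conditional inference forest of the scaled regional signal on
#' the timing design — prenatal exposure, one binary predictor per year
#' of age, and exposure duration as a confound control — then computes
#' permutation importances, the re-randomization max-importance test over
#' the age bins ("at any age"), marginal per-age p-values with BH-FDR
#' correction, an optional combined-window test, and the correlation of
#' out-of-bag predictions with the actual scaled response.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param response_name response column (default `"gm_signal"`).
#' @param run_config list overriding `n_trees` (200), `mtry` (4),
#'   `subsample_fraction` (0.632), `B` (199), `n_perm` (1), `seed` (1),
#'   `window` (`NULL`: no combined test).
#' @return an `analysis_report`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 60, effect_size = 2,
#'                                      seed = 3))
#' rep <- run_timing_analysis(cohort,
#'   run_config = list(n_trees = 50, B = 49, seed = 3))
#' rep$rerand$max_test$peak
#' @export
run_timing_analysis <- function(cohort, response_name = "gm_signal",
                                run_config = list()) {
  age_cols <- grep("^age_\\d+_\\d+$", names(cohort), value = TRUE)
  age_cols <- age_cols[order(as.integer(sub("^age_(\\d+)_.*$", "\\1", age_cols)))]
  preds <- c("prenatal_dv", age_cols, "duration_years")
  run_design(cohort, response_name, preds, max_over = age_cols,
             design = "timing", run_config = run_config)
}

#' Maltreatment-type analysis
#'
#' Forest of the scaled signal on the four maltreatment-type indicators
#' plus the number of types; the max-importance statistic spans all five
#' predictors.
#'
#' @inheritParams run_timing_analysis
#' @return an `analysis_report`.
#' @export
run_type_analysis <- function(cohort, response_name = "gm_signal",
                              run_config = list()) {
  preds <- unname(type_predictors())
  run_design(cohort, response_name, preds, max_over = preds,
             design = "type", run_config = run_config)
}

#' Symptom (TSCC subscale) analyses
#'
#' Runs the timing design once per symptom subscale response, with FDR
#' correction across ages within each subscale.  Missing subscales are
#' skipped with a warning and recorded.
#'
#' @param cohort a cohort data frame.
#' @param subscale_names response columns; default the six TSCC subscales.
#' @param run_config as in [run_timing_analysis()].
#' @return a `symptom_reports` list of `analysis_report`s, one per
#'   subscale found, with attribute `skipped`.
#' @export
run_symptom_analysis <- function(cohort,
                                 subscale_names = c("tscc_anx", "tscc_dep",
                                                    "tscc_ang", "tscc_pts",
                                                    "tscc_dis", "tscc_sc"),
                                 run_config = list()) {
  present <- intersect(subscale_names, names(cohort))
  skipped <- setdiff(subscale_names, present)
  if (length(skipped))
    warning("subscales missing from cohort, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  reports <- lapply(present, function(sc)
    run_timing_analysis(cohort, response_name = sc, run_config = run_config))
  names(reports) <- present
  structure(reports, skipped = skipped, class = "symptom_reports")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("%s-design analysis of '%s' (n = %d, %d trees, B = %d)\n",
              x$design, x$response, x$n, x$run_config$n_trees,
              x$run_config$B))
  top <- x$importance[order(-x$importance$importance), ][1:3, ]
  cat("  top importances:",
      paste(sprintf("%s (%.3g)", top$predictor, top$importance),
            collapse = ", "), "\n")
  cat(sprintf("  peak %s: p_max = %.4g\n",
              x$rerand$max_test$peak, x$rerand$max_test$p_value))
  cat(sprintf("  OOB prediction r = %.3f\n", x$prediction_r))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes the importance table, the re-randomization p/q tables, null
#' summary quantiles, the OOB prediction correlation and the full run
#' configuration; given an identical cohort and configuration the file is
#' byte-identical across runs.
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  rr <- report$rerand
  obj <- list(
    design = report$design,
    response = report$response,
    n = report$n,
    run_config = report$run_config[c("n_trees", "mtry",
                                     "subsample_fraction", "B", "n_perm",
                                     "seed")],
    window = report$run_config$window,
    predictors = report$predictors,
    importance = as.data.frame(report$importance),
    max_test = rr$max_test,
    p_per_predictor = as.list(rr$p_per_predictor),
    q_per_predictor = as.list(rr$q_per_predictor),
    combined = rr$combined,
    null_quantiles = apply(rr$null_quantiles, 2, as.list),
    prediction_r = report$prediction_r,
    oob_mse = report$oob_mse
  )
  jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
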