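small_fit <- function(n = 60, seed = 1, effect = 1.5) {
  co <- simulate_cohort(sim_config(n_subjects = n, effect_size = effect,
                                   seed = seed))
  X <- as.matrix(co[, timing_predictors()])
  y <- scale_signal(co$gm_signal)
  cfg <- forest_config(n_trees = 25, seed = seed)
  forest <- fit_forest(X, y, cfg)
  list(X = X, y = y, cfg = cfg, forest = forest,
       imp = permutation_importance(forest))
}

test_that("the re-randomization null is reproducible and leaves X intact", {
  d <- small_fit()
  X_before <- d$X
  n1 <- rerandomization_null(d$X, d$y, config = d$cfg, B = 3, seed = 7)
  n2 <- rerandomization_null(d$X, d$y, config = d$cfg, B = 3, seed = 7)
  expect_identical(n1, n2)
  expect_identical(d$X, X_before)
  expect_equal(dim(n1), c(3L, ncol(d$X)))
  expect_equal(colnames(n1), colnames(d$X))
  expect_error(rerandomization_null(d$X, d$y, config = d$cfg, B = 0), "B")
})

test_that("max-importance test follows the add-one estimator", {
  obs <- c(a = 5, b = 1)
  null_low <- matrix(runif(40, 0, 0.5), 20, 2,
                     dimnames = list(NULL, c("a", "b")))
  r <- max_importance_test(obs, null_low)
  expect_equal(r$p_value, 1 / 21)
  expect_equal(r$peak, "a")
  expect_equal(r$statistic, 5)

  null_high <- matrix(runif(40, 10, 11), 20, 2,
                      dimnames = list(NULL, c("a", "b")))
  expect_equal(max_importance_test(obs, null_high)$p_value, 1)
  expect_error(max_importance_test(obs, null_low, character(0)), "empty")
})

test_that("a singleton max test equals the marginal p-value", {
  d <- small_fit(seed = 3)
  nm <- rerandomization_null(d$X, d$y, config = d$cfg, B = 19, seed = 3)
  p_marg <- per_predictor_pvalues(d$imp, nm)
  for (col in c("age_5_6", "duration_years")) {
    expect_equal(max_importance_test(d$imp, nm, col)$p_value,
                 unname(p_marg[col]))
  }
  expect_length(p_marg, ncol(nm))
  expect_true(all(p_marg > 0 & p_marg <= 1))
  # observed below its whole null column gives p = 1
  obs <- setNames(rep(-Inf, ncol(nm)), colnames(nm))
  expect_true(all(per_predictor_pvalues(obs, nm) == 1))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("combined-window test uses a max-over-windows null", {
  obs <- c(w1 = 1, w2 = 2, w3 = 3, w4 = 0.5)
  nm <- matrix(c(1, 0, 0, 0,
                 0, 0, 3, 3,
                 2, 2, 2, 2), 3, 4, byrow = TRUE,
               dimnames = list(NULL, names(obs)))
  r <- combined_window_test(obs, nm, c("w2", "w3"))
  expect_equal(r$statistic, 5)
  # per-row maxima over length-2 windows: 1, 6, 4 -> one null >= 5
  expect_equal(r$p_value, 2 / 4)
  expect_error(combined_window_test(obs, nm, c("w1", "w3")), "contiguous")
  expect_error(combined_window_test(obs, nm, "nope"), "not found")
  # window spanning everything compares against full-row sums: 1, 6, 8
  r_all <- combined_window_test(obs, nm, names(obs))
  expect_equal(r_all$statistic, 6.5)
  expect_equal(r_all$p_value, 2 / 4)
  # observed sum above every null max hits the add-one floor
  obs_big <- c(w1 = 99, w2 = 99, w3 = 99, w4 = 99)
  expect_equal(combined_window_test(obs_big, nm, c("w1", "w2"))$p_value, 1 / 4)
})

test_that("rerand_analysis assembles consistent p, q and combined results", {
  d <- small_fit(seed = 5, n = 80)
  age_cols <- grep("^age_", colnames(d$X), value = TRUE)
  rr <- rerand_analysis(d$imp, d$X, d$y, config = d$cfg, max_over = age_cols,
                        B = 29, seed = 5,
                        window = c("age_5_6", "age_6_7"))
  expect_s3_class(rr, "rerand_result")
  expect_length(rr$p_per_predictor, length(age_cols))
  expect_true(all(rr$q_per_predictor >= rr$p_per_predictor - 1e-12))
  expect_gte(rr$max_test$p_value, 1 / 30)
  expect_equal(rr$combined$window, c("age_5_6", "age_6_7"))
  expect_output(print(rr), "peak predictor")
})

test_that("null cohorts keep observed importances inside their null bands", {
  inside <- 0L; total <- 0L
  for (s in 1:6) {
    co <- simulate_cohort(null_config(80, seed = 600 + s))
    X <- as.matrix(co[, timing_predictors()])
    y <- scale_signal(co$gm_signal)
    cfg <- forest_config(n_trees = 25, seed = s)
    forest <- fit_forest(X, y, cfg)
    imp <- permutation_importance(forest)
    nm <- rerandomization_null(X, y, config = cfg, B = 39, seed = s)
    lo <- apply(nm, 2, quantile, 0.025)
    hi <- apply(nm, 2, quantile, 0.975)
    v <- setNames(imp$importance, imp$predictor)
    inside <- inside + sum(v >= lo & v <= hi)
    total <- total + length(v)
  }
  expect_gte(inside / total, 0.85)  # ~95% coverage, Monte-Carlo slack
})
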