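test_that("association statistic handles degenerate and orthogonal inputs", {
  expect_equal(linear_association_statistic(rep(2, 5), rnorm(5)),
               list(statistic = 0, p_value = 1))
  expect_equal(linear_association_statistic(rnorm(5), rep(1, 5))$p_value, 1)
  # orthogonal: T = sum x (y - ybar) = 0
  expect_equal(linear_association_statistic(c(1, 0, 1, 0), c(1, 1, -1, -1)),
               list(statistic = 0, p_value = 1))
  expect_error(linear_association_statistic(1:3, 1:4), "same length")
  expect_error(linear_association_statistic(1, 1), "at least two")
})

test_that("statistic uses the exact conditional variance", {
  # x = y = (0,0,1,1): T = 1, Sxx = Syy = 1, Var = 1/3, z = sqrt(3)
  r <- linear_association_statistic(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(r$statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-sqrt(3)), tolerance = 1e-12)
  # exhaustive-permutation p for this instance is 2/6
  expect_equal(exact_assoc_p(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1 / 3)
})

test_that("conditional moments match the exhaustive permutation law exactly", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    xc <- x - mean(x)
    P <- all_perms(seq_len(n))
    t_perm <- apply(P, 1, function(pr) sum(xc * (y[pr] - mean(y))))
    v_exact <- mean(t_perm^2)  # permutation mean is identically 0
    expect_lt(abs(mean(t_perm)), 1e-9)
    z <- linear_association_statistic(x, y)$statistic
    t_obs <- abs(sum(xc * (y - mean(y))))
    if (z == 0) next
    # implied variance t_obs^2 / z^2 equals the exhaustive variance
    expect_equal(t_obs^2 / z^2, v_exact, tolerance = 1e-10)
  }
})

test_that("asymptotic p-values track the exhaustive permutation oracle", {
  # the normal approximation to the discrete permutation law is documented
  # to agree within 0.4 for n >= 6 (it is qualitative only below that)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:8, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    p_asym <- linear_association_statistic(x, y)$p_value
    expect_lt(abs(p_asym - exact_assoc_p(x, y)), 0.4)
  }
})

test_that("variable selection picks the smallest p-value, ties to low index", {
  X <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  y <- rnorm(20)
  expect_equal(select_split_variable(X, y, 2)$chosen, 2)
  # duplicated column: identical p-values, smallest index wins
  X2 <- cbind(X[, 1], X[, 1], X[, 2])
  sel <- select_split_variable(X2, X2[, 1] + 0.1 * rnorm(20), 1:3)
  expect_equal(sel$chosen, 1)
  expect_error(select_split_variable(X, y, integer(0)), "empty")
  # all-constant candidates report p-values of 1
  Xc <- matrix(1, 10, 2)
  expect_equal(unname(select_split_variable(Xc, rnorm(10), 1:2)$p_values),
               c(1, 1))
})

test_that("the truly associated candidate is selected almost surely", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    X <- cbind(rnorm(30), rnorm(30), rnorm(30))
    j <- 2L
    y <- X[, j]
    if (select_split_variable(X, y, 1:3)$chosen == j) hits <- hits + 1L
  }
  expect_gte(hits, 198L)  # >= 99%
})

test_that("best split matches brute force and respects min_bucket", {
  r <- best_binary_split(c(1, 2, 3, 4), c(0, 0, 10, 10), min_bucket = 1)
  expect_equal(r$threshold, 2.5)
  # binary predictor: the single admissible cutpoint
  r2 <- best_binary_split(c(0, 1, 0, 1), c(1, 5, 2, 6), min_bucket = 1)
  expect_equal(r2$threshold, 0.5)
  # no admissible partition
  expect_null(best_binary_split(1:4, rnorm(4), min_bucket = 3))

  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:9, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- round(rnorm(n), 2)
    mb <- sample(1:2, 1)
    got <- best_binary_split(x, y, mb)
    want <- brute_split(x, y, mb)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    }
  }
})

test_that("degenerate responses give root-only trees predicting the mean", {
  X <- cbind(rnorm(12))
  fit <- fit_ctree(X, rep(3.5, 12), ctree_params(mtry = 1, min_split = 2,
                                                 min_bucket = 1))
  expect_equal(nrow(fit$nodes), 1)
  expect_equal(predict(fit, X), rep(3.5, 12))

  y <- rnorm(12)
  fit2 <- fit_ctree(X, y, ctree_params(mtry = 1, min_split = 50))
  expect_equal(nrow(fit2$nodes), 1)
  expect_equal(predict(fit2, X), rep(mean(y), 12))

  expect_error(fit_ctree(cbind(c(1, NA, 3)), 1:3), "missing values")
})

test_that("a perfectly separating binary predictor yields a depth-1 tree", {
  X <- cbind(g = c(0, 0, 0, 1, 1, 1))
  y <- c(1, 1, 1, 9, 9, 9)
  fit <- fit_ctree(X, y, ctree_params(mtry = 1, min_split = 2, min_bucket = 1))
  expect_equal(tree_depth(fit), 1)
  expect_equal(sort(unique(predict(fit, X))), c(1, 9))
  # tie convention: a case exactly at the threshold goes left
  expect_equal(predict(fit, cbind(g = 0.5)), 1)
})

test_that("terminal predictions equal node means and children account for n", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60)
  y <- X[, 1] + rnorm(60)
  fit <- fit_ctree(X, y, ctree_params(mtry = 2, min_split = 6, min_bucket = 2),
                   seed = 3)
  nodes <- fit$nodes
  expect_gt(nrow(nodes), 1)
  pred <- predict(fit, X)
  for (i in which(is.na(nodes$split_var))) {
    members <- abs(pred - nodes$prediction[i]) < 1e-12
    if (any(members))
      expect_equal(mean(y[members]), nodes$prediction[i], tolerance = 1e-10)
  }
  internal <- which(!is.na(nodes$split_var))
  expect_equal(nodes$n[internal],
               nodes$n[nodes$left[internal]] + nodes$n[nodes$right[internal]])
  # refinement: a grown tree never fits training data worse than the root
  expect_lte(mean((y - pred)^2), mean((y - mean(y))^2))
})

test_that("smaller alpha never grows a deeper tree on the same data and seed", {
  for (s in 1:8) {
    set.seed(s)
    X <- matrix(rnorm(40 * 3), 40)
    y <- X[, 1] + rnorm(40)
    depths <- vapply(c(0.01, 0.2, 1), function(a)
      tree_depth(fit_ctree(X, y, ctree_params(mtry = 2, min_split = 4,
                                              min_bucket = 2, alpha = a),
                           seed = s)),
      numeric(1))
    expect_true(all(diff(depths) >= 0))
  }
})

test_that("trees serialize to JSON with named splits", {
  X <- cbind(g = c(0, 0, 0, 1, 1, 1))
  fit <- fit_ctree(X, c(1, 1, 1, 9, 9, 9),
                   ctree_params(mtry = 1, min_split = 2, min_bucket = 1))
  js <- jsonlite::fromJSON(tree_to_json(fit))
  expect_equal(js$columns, "g")
  expect_equal(js$nodes$split_name[1], "g")
})
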