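# Independent oracles used against the compiled tree engine.

# all permutations of a vector (rows), exhaustive
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_len(n), function(i) cbind(v[i], all_perms(v[-i]))))
}

# exact two-sided permutation p-value for the linear statistic
# T = sum x_i (y_i - ybar), enumerating every reassignment of y
exact_assoc_p <- function(x, y) {
  xc <- x - mean(x)
  t_obs <- abs(sum(xc * (y - mean(y))))
  P <- all_perms(seq_along(y))
  t_perm <- apply(P, 1, function(pr) abs(sum(xc * (y[pr] - mean(y)))))
  mean(t_perm >= t_obs - 1e-9)
}

# brute-force split search: evaluate every midpoint between consecutive
# distinct x values directly from the statistic's definition
brute_split <- function(x, y, min_bucket) {
  ux <- sort(unique(x))
  n <- length(y)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)
  if (length(ux) < 2 || syy <= 1e-12) return(NULL)
  best <- NULL
  for (k in seq_len(length(ux) - 1)) {
    thr <- (ux[k] + ux[k + 1]) / 2
    left <- x <= thr
    nl <- sum(left)
    nr <- n - nl
    if (nl < min_bucket || nr < min_bucket) next
    z <- abs(sum((y - ybar)[left])) / sqrt(nl * nr / n * syy / (n - 1))
    if (is.null(best) || z > best$statistic + 1e-12)
      best <- list(threshold = thr, statistic = z)
  }
  best
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{k >= i} p_(k) * m / k, capped at 1, back in input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ks <- i:m
    q[o[i]] <- min(1, min(p[o[ks]] * m / ks))
  }
  q
}

# small helper: cohort configured to carry no signal at all
null_config <- function(n, seed, max_age_bin = 16) {
  sim_config(n_subjects = n, max_age_bin = max_age_bin,
             effect_size = 0, type_effect = 0, seed = seed)
}
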