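test_that("two-node partial correlation equals the Pearson correlation", {
  set.seed(41)
  x <- matrix(rnorm(200 * 2), 200, 2)
  x[, 2] <- x[, 1] * 0.6 + x[, 2]
  pc <- partial_correlation(x, estimator = "empirical")
  expect_equal(pc[1, 2], cor(x[, 1], x[, 2]), tolerance = 1e-12)
  expect_equal(diag(unclass(pc)), c(node_1 = 0, node_2 = 0),
               ignore_attr = TRUE)
})

test_that("partial correlation suppresses chain-induced indirect coupling", {
  set.seed(42)
  t_len <- 2000
  x1 <- rnorm(t_len)
  x2 <- x1 + rnorm(t_len)
  x3 <- x2 + rnorm(t_len)
  x <- cbind(x1, x2, x3)
  pc <- partial_correlation(x, estimator = "empirical")
  expect_gt(cor(x1, x3), 0.3)
  expect_lt(abs(pc[1, 3]), 0.1)
})

test_that("empirical partial correlation matches the regression-residual oracle", {
  set.seed(43)
  sigma <- diag(5) * 0.6 + 0.4
  x <- matrix(rnorm(500 * 5), 500, 5) %*% chol(sigma)
  pc <- partial_correlation(x, estimator = "empirical")
  expect_lt(max(abs(unclass(pc) - pcor_oracle(x))), 1e-8)
})

test_that("singular empirical covariance raises an error advising shrinkage", {
  set.seed(44)
  x <- matrix(rnorm(10 * 20), 10, 20)  # frames < nodes
  expect_error(partial_correlation(x, estimator = "empirical"),
               class = "rpnsig_error_singular")
  # shrinkage handles the same data
  pc <- partial_correlation(x, estimator = "shrinkage")
  expect_true(all(abs(unclass(pc)[upper.tri(pc)]) <= 1))
})

test_that("partial correlation is invariant to per-node affine rescaling", {
  set.seed(45)
  x <- matrix(rnorm(300 * 4), 300, 4)
  pc <- partial_correlation(x, estimator = "empirical")
  x2 <- x; x2[, 2] <- 10 * x2[, 2] + 3
  pc2 <- partial_correlation(x2, estimator = "empirical")
  expect_equal(unclass(pc2), unclass(pc), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("estimates converge to the analytic partial correlation of a known precision", {
  set.seed(46)
  p <- 6
  theta <- diag(p)
  theta[1, 2] <- theta[2, 1] <- 0.4
  theta[3, 5] <- theta[5, 3] <- -0.3
  analytic <- -theta / tcrossprod(sqrt(diag(theta)))
  diag(analytic) <- 0
  x <- matrix(rnorm(5000 * p), 5000, p) %*% chol(solve(theta))
  for (est in c("empirical", "shrinkage")) {
    pc <- partial_correlation(x, estimator = est)
    expect_lt(max(abs(unclass(pc) - analytic)), 0.05)
  }
})

test_that("Ledoit-Wolf shrinkage is well-behaved", {
  set.seed(47)
  x <- matrix(rnorm(40 * 10), 40, 10)
  s <- ledoit_wolf_cov(x)
  expect_gte(attr(s, "shrinkage"), 0)
  expect_lte(attr(s, "shrinkage"), 1)
  expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  # for a non-spherical truth the shrinkage vanishes as n grows and the
  # estimate approaches the empirical covariance
  xl <- matrix(rnorm(20000 * 5), 20000, 5) %*% diag(c(3, 2, 1, 0.5, 0.2))
  expect_lt(attr(ledoit_wolf_cov(xl), "shrinkage"), 0.01)
  n <- nrow(xl)
  expect_equal(unname(ledoit_wolf_cov(xl)), unname(cov(xl) * (n - 1) / n),
               tolerance = 1e-2, ignore_attr = TRUE)
  # a spherical truth (already equal to the target) draws far more
  # shrinkage than a strongly non-spherical one at the same sample size
  xs <- matrix(rnorm(2000 * 5), 2000, 5)
  xn <- matrix(rnorm(2000 * 5), 2000, 5) %*% diag(c(3, 2, 1, 0.5, 0.2))
  expect_gt(attr(ledoit_wolf_cov(xs), "shrinkage"),
            10 * attr(ledoit_wolf_cov(xn), "shrinkage"))
})

test_that("upper-triangle vectorization has the documented size and index map", {
  expect_equal(nrow(vectorize_upper(rand_symmetric(123))), 7503)
  expect_equal(nrow(vectorize_upper(rand_symmetric(3))), 3)
  # closed-form feature index: i*(2n-i-1)/2 + (j-i-1), 0-based
  for (n in c(3, 10, 123)) {
    map <- feature_index_map(n)
    i0 <- map$node_i - 1; j0 <- map$node_j - 1
    expect_equal(map$feature_index, i0 * (2 * n - i0 - 1) / 2 + (j0 - i0 - 1) + 1)
    expect_equal(nrow(map), n * (n - 1) / 2)
    expect_false(anyDuplicated(map$feature_index) > 0)
  }
})

test_that("vectorize is row-major over i < j and round-trips exactly", {
  m <- rand_symmetric(5, seed = 48)
  fv <- vectorize_upper(m)
  # row-major traversal: first n-1 features come from row 1
  expect_equal(fv$value[1:4], unname(m[1, 2:5]))
  expect_equal(fv$value[5:7], unname(m[2, 3:5]))
  back <- devectorize(fv)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
  expect_error(devectorize(rnorm(5), labels = paste0("n", 1:4)),
               class = "rpnsig_error_invalid_input")
})

test_that("module ordering groups nodes into contiguous blocks and is invertible", {
  m <- rand_symmetric(6, seed = 49)
  modules <- c("B", "A", "B", "A", "C", "B")
  conn2 <- structure(m, class = c("conn_matrix", "matrix"), modules = modules,
                     estimator = "test")
  ord <- order_by_modules(conn2)
  perm <- attr(ord, "permutation")
  # stable grouping in first-appearance order
  expect_equal(attr(ord, "modules"), c("B", "B", "B", "A", "A", "C"))
  expect_equal(perm, c(1, 3, 6, 2, 4, 5))
  # direct permutation-matrix oracle
  pmat <- diag(6)[perm, ]
  expect_equal(unclass(ord), pmat %*% m %*% t(pmat), ignore_attr = TRUE)
  # applying the inverse permutation restores the input
  inv <- order(perm)
  expect_equal(unclass(ord)[inv, inv], m, ignore_attr = TRUE)
  # single module: identity permutation
  one <- order_by_modules(conn2, modules = rep("A", 6))
  expect_equal(attr(one, "permutation"), 1:6)
})

test_that("node predictive strength sums incident weights", {
  sig <- rpnsig:::new_pain_signature(
    tibble::tibble(feature_index = 1:2, label_i = c("A", "A"),
                   label_j = c("B", "C"), weight = c(0.5, -0.2),
                   median = NA_real_, iqr = NA_real_),
    mode = "weights_only"
  )
  st <- node_predictive_strength(sig)
  expect_equal(st$strength[st$node == "A"], 0.3)
  expect_equal(st$strength[st$node == "B"], 0.5)
  expect_equal(st$strength[st$node == "C"], -0.2)
  # nodes outside the signature get zero strength
  st2 <- node_predictive_strength(sig, nodes = c("A", "B", "C", "D"))
  expect_equal(st2$strength[st2$node == "D"], 0)
})

test_that("the packaged signature's global grey-matter strength is its single incident weight", {
  sig <- rpn_signature()
  st <- node_predictive_strength(sig)
  expect_equal(st$strength[st$node == "mean GM"], -0.086)
})
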