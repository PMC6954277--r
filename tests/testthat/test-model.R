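test_that("extreme regularisation yields the null model", {
  set.seed(61)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  fit <- fit_pipeline(x, y, pipeline_hp(k_best = 10, l1_ratio = 0.9, alpha = 1e6))
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, mean(y), tolerance = 1e-10)
  expect_equal(predict(fit, x), rep(mean(y), 40), tolerance = 1e-10)
})

test_that("a planted univariate signal is selected and predicts held-out data", {
  set.seed(62)
  n <- 100; p <- 60
  x <- matrix(rnorm(n * p), n, p)
  y <- 2 * x[, 5] + rnorm(n, sd = 0.2)
  fit <- fit_pipeline(x, y, pipeline_hp(k_best = 10, l1_ratio = 0.9, alpha = 0.01))
  expect_true(5 %in% fit$selected)
  w5 <- fit$weights[match(5, fit$selected)]
  expect_gt(w5, 0)
  x_new <- matrix(rnorm(50 * p), 50, p)
  y_new <- 2 * x_new[, 5] + rnorm(50, sd = 0.2)
  expect_gt(cor(y_new, predict(fit, x_new)), 0.9)
})

test_that("fitted solutions satisfy the elastic-net KKT conditions", {
  set.seed(63)
  x <- matrix(rnorm(50 * 40), 50, 40)
  y <- x[, 1] - 0.5 * x[, 7] + rnorm(50, sd = 0.5)
  grid <- expand.grid(k = c(5, 20, 40), rho = c(0.1, 0.9, 1), a = c(0.001, 0.05, 0.5))
  for (g in seq_len(nrow(grid))) {
    fit <- fit_pipeline(x, y, pipeline_hp(grid$k[g], grid$rho[g], grid$a[g]))
    expect_lt(kkt_residual(fit, x, y), 1e-4)
  }
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pipeline(x, rep(1, 10)), class = "rpnsig_error_degenerate_target")
  expect_error(fit_pipeline(x, rnorm(10), pipeline_hp(k_best = 5)),
               class = "rpnsig_error_config")
  expect_error(fit_pipeline(x[1:3, ], rnorm(3)), class = "rpnsig_error_invalid_input")
})

test_that("robust scaling absorbs per-feature affine transforms of the input", {
  set.seed(64)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 3] - x[, 11] + rnorm(n, sd = 0.3)
  hp <- pipeline_hp(k_best = 8, l1_ratio = 0.9, alpha = 0.01)
  fit1 <- fit_pipeline(x, y, hp)
  scale_f <- runif(p, 0.5, 3); shift_f <- rnorm(p, sd = 2)
  x2 <- sweep(sweep(x, 2, scale_f, "*"), 2, shift_f, "+")
  fit2 <- fit_pipeline(x2, y, hp)
  expect_equal(predict(fit2, x2), predict(fit1, x), tolerance = 1e-6)
})

test_that("LOO grid search produces n folds and matches direct evaluation on one cell", {
  set.seed(65)
  n <- 24; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 2] + rnorm(n, sd = 0.5)
  hp <- pipeline_hp(k_best = 6, l1_ratio = 0.9, alpha = 0.05)
  gs <- loo_grid_search(x, y, hyperparam_grid(k_values = 6, l1_ratios = 0.9,
                                              alphas = 0.05))
  expect_equal(nrow(gs$predictions), n)  # one fold per participant
  direct <- vapply(seq_len(n), function(i) {
    f <- fit_pipeline(x[-i, , drop = FALSE], y[-i], hp)
    predict(f, x[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(gs$predictions$y_cv, direct, tolerance = 1e-6)
  expect_equal(gs$best_hp$k_best, 6L)
})

test_that("grid search selects sensible cells and reports the full grid", {
  set.seed(66)
  n <- 30; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  y <- 1.5 * x[, 1] + rnorm(n, sd = 0.4)
  grid <- hyperparam_grid(k_values = c(5, 10, 300), l1_ratios = c(0.5, 0.999),
                          alphas = c(0.005, 0.5))
  expect_warning(gs <- loo_grid_search(x, y, grid), "exceeding")
  expect_equal(nrow(gs$grid_results), 2 * 2 * 2)  # k=300 dropped
  expect_s3_class(glance(gs), "tbl_df")
  expect_gt(gs$metrics$pearson_r, 0.5)
  expect_error(loo_grid_search(x[1:4, ], y[1:4], grid),
               class = "rpnsig_error_invalid_input")
})

test_that("learning curves are seed-reproducible with shrinking generalisation gap", {
  set.seed(67)
  n <- 100; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 1] - x[, 2] + rnorm(n, sd = 0.5)
  hp <- pipeline_hp(k_best = 5, l1_ratio = 0.9, alpha = 0.01)
  lc1 <- learning_curve(x, y, hp, train_fractions = c(0.2, 0.6), n_repeats = 8,
                        seed = 99)
  lc2 <- learning_curve(x, y, hp, train_fractions = c(0.2, 0.6), n_repeats = 8,
                        seed = 99)
  expect_equal(as.data.frame(lc1), as.data.frame(lc2))
  gap <- tapply(lc1$test_mse - lc1$train_mse, lc1$n_train, mean)
  expect_gt(gap[["20"]], gap[["60"]])  # overfitting shrinks with sample size
  expect_error(learning_curve(x, y, hp, train_fractions = 0.02),
               class = "rpnsig_error_invalid_input")
})

test_that("mean training error does not increase with training-set size", {
  set.seed(68)
  n <- 90; p <- 25
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 4] + rnorm(n, sd = 0.5)
  lc <- learning_curve(x, y, pipeline_hp(5, 0.9, 0.01),
                       train_fractions = c(0.3, 1), n_repeats = 20, seed = 3)
  tr <- tapply(lc$train_mse, lc$n_train, mean)
  sdv <- tapply(lc$train_mse, lc$n_train, sd)
  expect_lte(tr[[1]], tr[[2]] + max(sdv))
})

test_that("extract/apply round-trips the fitted pipeline exactly", {
  set.seed(69)
  n <- 50; nodes <- 8
  labels <- paste0("r", seq_len(nodes))
  feats <- t(replicate(n, {
    m <- matrix(rnorm(nodes^2), nodes); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(labels, labels)
    vectorize_upper(m)$value
  }))
  map <- feature_index_map(nodes)
  colnames(feats) <- paste0(labels[map$node_i], "--", labels[map$node_j])
  y <- feats[, 3] - 0.5 * feats[, 17] + rnorm(n, sd = 0.3)
  fit <- fit_pipeline(feats, y, pipeline_hp(k_best = 10, l1_ratio = 0.9, alpha = 0.01))
  sig <- extract_signature(fit, training_label = "test")
  expect_equal(nrow(sig), sum(fit$weights != 0))
  expect_equal(attr(sig, "mode"), "full")
  pred <- apply_signature(sig, feats)
  expect_equal(pred$prediction, predict(fit, feats), tolerance = 1e-10)
  # and via a single connectivity matrix
  one <- devectorize(feats[4, ], labels = labels)
  expect_equal(apply_signature(sig, one)$prediction, predict(fit, feats)[4],
               tolerance = 1e-10)
})

test_that("signature application follows the documented arithmetic", {
  sig <- rpnsig:::new_pain_signature(
    tibble::tibble(feature_index = 1L, label_i = "A", label_j = "B",
                   weight = 2, median = 0, iqr = 1),
    mode = "full", intercept = 0.5
  )
  m <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(apply_signature(sig, m)$prediction, 1.1)
  # empty signature predicts the intercept for every subject
  empty <- rpnsig:::new_pain_signature(
    tibble::tibble(feature_index = integer(), label_i = character(),
                   label_j = character(), weight = numeric(),
                   median = numeric(), iqr = numeric()),
    mode = "full", intercept = 0.5
  )
  expect_equal(apply_signature(empty, m)$prediction, 0.5)
  # missing node pairs are reported, not silently zeroed
  m2 <- matrix(0, 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(apply_signature(sig, m2), class = "rpnsig_error_missing_feature")
})

test_that("weights-only scores are an increasing affine map of full scores at equal IQRs", {
  set.seed(70)
  entries <- tibble::tibble(
    feature_index = 1:3, label_i = c("A", "A", "B"), label_j = c("B", "C", "C"),
    weight = c(0.5, -0.3, 0.2), median = c(0.1, -0.2, 0), iqr = c(2, 2, 2)
  )
  full <- rpnsig:::new_pain_signature(entries, mode = "full", intercept = 0.7)
  wo <- rpnsig:::new_pain_signature(dplyr::mutate(entries, median = NA, iqr = NA),
                                    mode = "weights_only")
  labels <- c("A", "B", "C")
  xs <- lapply(1:6, function(i) {
    m <- matrix(rnorm(9), 3); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(labels, labels); m
  })
  pf <- apply_signature(full, xs)$prediction
  pw <- apply_signature(wo, xs)$prediction
  expect_true(attr(apply_signature(wo, xs), "affine_relative"))
  f <- lm(pf ~ pw)
  expect_gt(coef(f)[2], 0)
  expect_lt(max(abs(resid(f))), 1e-10)
})

test_that("the packaged signature uses exactly its 21 connections on labelled input", {
  sig <- rpn_signature()
  labels <- unique(c(sig$label_i, sig$label_j, paste0("extra_", 1:5)))
  set.seed(71)
  m <- matrix(rnorm(length(labels)^2, sd = 0.1), length(labels))
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  pred <- apply_signature(sig, m)
  expect_equal(attr(pred, "n_connections_used"), 21)
  expect_true(attr(pred, "affine_relative"))
  expect_equal(pred$prediction,
               sum(sig$weight * m[cbind(sig$label_i, sig$label_j)]))
})

test_that("prediction metrics match hand-computed values and handle edge cases", {
  perfect <- prediction_metrics(1:5, 1:5)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$explained_variance, 1)
  expect_equal(perfect$pearson_r, 1)
  m <- prediction_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$explained_variance, 2 / 3)
  expect_equal(m$pearson_r, sqrt(3) / 2)
  # constant predictions: r undefined, explained variance still defined (0)
  const <- prediction_metrics(c(0, 1, 2, 3), rep(1, 4))
  expect_true(is.na(const$pearson_r))
  expect_equal(const$explained_variance, 0)
  expect_error(prediction_metrics(1:4, 1:5), class = "rpnsig_error_invalid_input")
})
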