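# The predictive pipeline: robust scaling -> K-best univariate selection ->
# elastic-net regression, with leave-one-subject-out hyperparameter search,
# learning curves, signature extraction and external application.

#' Pipeline hyperparameters
#'
#' @param k_best Number of features kept by univariate selection (>= 1).
#' @param l1_ratio Elastic-net mixing parameter in (0, 1]; 1 is the lasso.
#' @param alpha Overall regularisation weight (> 0).
#' @return A `pipeline_hp` list.
#' @export
pipeline_hp <- function(k_best = 25, l1_ratio = 0.999, alpha = 0.005) {
  if (k_best < 1) stop_config("`k_best` must be >= 1.")
  if (l1_ratio <= 0 || l1_ratio > 1) stop_config("`l1_ratio` must lie in (0, 1].")
  if (alpha <= 0) stop_config("`alpha` must be positive.")
  structure(list(k_best = as.integer(k_best), l1_ratio = l1_ratio, alpha = alpha),
            class = "pipeline_hp")
}

#' Hyperparameter grid
#'
#' Defaults reproduce the standard search space: K from 10 to 200 in steps
#' of 5, L1 ratios `{0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 0.999}` and alphas
#' `{0.001, 0.005, 0.01, 0.05, 0.1, 0.5}`.
#'
#' @param k_values,l1_ratios,alphas Numeric vectors of candidate values.
#' @return A `hyperparam_grid` list.
#' @export
hyperparam_grid <- function(k_values = seq(10, 200, by = 5),
                            l1_ratios = c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 0.999),
                            alphas = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5)) {
  if (!length(k_values) || !length(l1_ratios) || !length(alphas)) {
    stop_config("grid axes must be non-empty.")
  }
  if (any(k_values < 1) || any(l1_ratios <= 0 | l1_ratios > 1) || any(alphas <= 0)) {
    stop_config("grid contains invalid hyperparameter values.")
  }
  structure(list(k_values = sort(unique(as.integer(k_values))),
                 l1_ratios = sort(unique(l1_ratios)),
                 alphas = sort(unique(alphas))),
            class = "hyperparam_grid")
}

# internal building blocks --------------------------------------------------

robust_scale_fit <- function(x) {
  med <- apply(x, 2, median)
  q <- apply(x, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- q[2, ] - q[1, ]
  iqr[iqr == 0] <- 1
  list(center = med, scale = iqr)
}

robust_scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

# rank features by |Pearson r| with y; ties broken by ascending index
kbest_rank <- function(x, y) {
  r <- suppressWarnings(as.vector(cor(x, y)))
  r[is.na(r)] <- 0
  order(-abs(r), seq_along(r))
}

# 1-D elastic net (closed form), used when only one feature is selected
enet_1d <- function(x, y, alpha, l1_ratio) {
  n <- length(y)
  xm <- mean(x); ym <- mean(y)
  xc <- x - xm; yc <- y - ym
  c1 <- sum(xc * yc) / n
  m2 <- sum(xc^2) / n
  st <- sign(c1) * max(abs(c1) - alpha * l1_ratio, 0)
  w <- if (m2 + alpha * (1 - l1_ratio) == 0) 0 else st / (m2 + alpha * (1 - l1_ratio))
  list(w = w, b = ym - w * xm)
}

# cyclic coordinate descent on the elastic-net objective, warm-started from
# an approximate solution; iterates until the KKT subgradient residual is
# below `tol`, so fitted pipelines are certifiably optimal
enet_cd <- function(x, y, alpha, l1_ratio, w, tol = 1e-8, max_pass = 5000) {
  n <- nrow(x); p <- ncol(x)
  lam1 <- alpha * l1_ratio; lam2 <- alpha * (1 - l1_ratio)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  col_ss <- colSums(xc^2) / n
  r <- yc - as.numeric(xc %*% w)
  for (pass in seq_len(max_pass)) {
    for (j in seq_len(p)) {
      if (col_ss[j] == 0) next
      cj <- sum(xc[, j] * r) / n + col_ss[j] * w[j]
      wj <- sign(cj) * max(abs(cj) - lam1, 0) / (col_ss[j] + lam2)
      if (wj != w[j]) {
        r <- r + xc[, j] * (w[j] - wj)
        w[j] <- wj
      }
    }
    g <- -crossprod(xc, r) / n + lam2 * w
    viol <- max(c(abs(g[w != 0] + lam1 * sign(w[w != 0])),
                  pmax(abs(g[w == 0]) - lam1, 0), 0))
    if (viol < tol) break
  }
  list(weights = as.numeric(w), intercept = ym - sum(xm * w))
}

# elastic net at a fixed penalty: glmnet along a lambda path for speed,
# then coordinate-descent polish to certifiable KKT optimality
enet_fit <- function(x, y, alpha, l1_ratio) {
  n <- nrow(x)
  if (ncol(x) == 1) {
    f <- enet_1d(x[, 1], y, alpha, l1_ratio)
    return(list(weights = f$w, intercept = f$b))
  }
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(x - rep(colMeans(x), each = n), yc))) / (n * l1_ratio)
  if (!is.finite(lmax) || lmax <= alpha) {
    w0 <- numeric(ncol(x))
  } else {
    path <- exp(seq(log(lmax), log(alpha), length.out = 40))
    path[length(path)] <- alpha
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = l1_ratio,
                          lambda = path, standardize = FALSE,
                          thresh = 1e-10, maxit = 1e6)
    w0 <- as.numeric(coef(fit, s = alpha, exact = FALSE))[-1]
  }
  enet_cd(x, y, alpha, l1_ratio, w0)
}

#' Fit the scale / select / elastic-net pipeline
#'
#' The three stages, fitted on the training data only:
#' \enumerate{
#'   \item robust per-feature scaling `(x - median) / (Q75 - Q25)` (scale 1
#'     where the IQR is 0);
#'   \item keep the `k_best` features with largest univariate `|Pearson r|`
#'     with the target (ties broken by ascending feature index);
#'   \item elastic net minimising
#'     `1/(2n) * RSS + alpha * l1_ratio * ||w||_1 +
#'      alpha * (1 - l1_ratio)/2 * ||w||^2` with an unpenalised intercept.
#' }
#'
#' @param x Subjects x features numeric matrix. Column names of the form
#'   `"<label_i>--<label_j>"` (as produced by [cohort_features()]) let
#'   [extract_signature()] recover node pairs.
#' @param y Numeric target scores, one per subject.
#' @param hp A [pipeline_hp()] object.
#' @return A fitted `pain_pipeline` object.
#' @export
fit_pipeline <- function(x, y, hp = pipeline_hp()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_invalid("`x` and `y` disagree on subject count.")
  if (length(y) < 4) stop_invalid("at least 4 subjects are required.")
  check_finite(x, "x"); check_finite(y, "y")
  if (sd(y) == 0) {
    abort("the target is constant; nothing to predict.",
          class = c("rpnsig_error_degenerate_target", "rpnsig_error"))
  }
  if (hp$k_best > ncol(x)) {
    stop_config(sprintf("k_best = %d exceeds the %d available features.",
                        hp$k_best, ncol(x)))
  }
  sc <- robust_scale_fit(x)
  xs <- robust_scale_apply(x, sc)
  ranked <- kbest_rank(xs, y)
  selected <- sort(ranked[seq_len(hp$k_best)])
  fit <- enet_fit(xs[, selected, drop = FALSE], y, hp$alpha, hp$l1_ratio)
  structure(
    list(hp = hp, center = sc$center, scale = sc$scale,
         selected = selected, weights = fit$weights,
         intercept = fit$intercept,
         feature_names = colnames(x), n = length(y)),
    class = "pain_pipeline"
  )
}

#' @export
print.pain_pipeline <- function(x, ...) {
  cat(sprintf(
    "Pain-prediction pipeline: n = %d, K = %d, l1_ratio = %g, alpha = %g\n",
    x$n, x$hp$k_best, x$hp$l1_ratio, x$hp$alpha))
  cat(sprintf("  non-zero weights: %d of %d selected features\n",
              sum(x$weights != 0), length(x$selected)))
  invisible(x)
}

#' @export
predict.pain_pipeline <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center)) {
    stop_invalid("`newdata` has a different feature count than the training data.")
  }
  xs <- robust_scale_apply(x, list(center = object$center, scale = object$scale))
  as.numeric(xs[, object$selected, drop = FALSE] %*% object$weights +
               object$intercept)
}

#' @export
tidy.pain_pipeline <- function(x, ...) {
  nm <- if (is.null(x$feature_names)) paste0("f", x$selected) else x$feature_names[x$selected]
  tibble(feature_index = x$selected, term = nm, weight = x$weights)
}

#' @export
glance.pain_pipeline <- function(x, ...) {
  tibble(n = x$n, k_best = x$hp$k_best, l1_ratio = x$hp$l1_ratio,
         alpha = x$hp$alpha, n_nonzero = sum(x$weights != 0),
         intercept = x$intercept)
}

#' Elastic-net KKT optimality residual
#'
#' Certifies a fitted pipeline against the subgradient optimality
#' conditions of its elastic-net objective: for selected features with
#' non-zero weight the penalised gradient must vanish; for zero-weight
#' features its magnitude must not exceed the L1 penalty; the mean residual
#' (intercept condition) must be 0.
#'
#' @param fit A `pain_pipeline`.
#' @param x,y The training data the pipeline was fitted on.
#' @return The largest KKT violation (0 = exactly optimal).
#' @export
kkt_residual <- function(fit, x, y) {
  x <- as.matrix(x)
  xs <- robust_scale_apply(x, list(center = fit$center, scale = fit$scale))
  xsel <- xs[, fit$selected, drop = FALSE]
  n <- length(y)
  r <- y - as.numeric(xsel %*% fit$weights + fit$intercept)
  g <- -crossprod(xsel, r) / n + fit$hp$alpha * (1 - fit$hp$l1_ratio) * fit$weights
  lam <- fit$hp$alpha * fit$hp$l1_ratio
  viol_nz <- abs(g[fit$weights != 0] + lam * sign(fit$weights[fit$weights != 0]))
  viol_z <- pmax(abs(g[fit$weights == 0]) - lam, 0)
  max(c(abs(mean(r)), viol_nz, viol_z, 0))
}

# leave-one-out grid search --------------------------------------------------

#' Leave-one-subject-out hyperparameter grid search
#'
#' For every grid cell the complete pipeline (scaling, selection,
#' regression) is refitted on n-1 subjects and the left-out subject is
#' predicted; the cell minimising the mean squared LOO error wins. Ties are
#' broken towards smaller `k_best`, then larger `alpha`, then smaller
#' `l1_ratio` (the more parsimonious model).
#'
#' @param x Subjects x features matrix.
#' @param y Numeric scores.
#' @param grid A [hyperparam_grid()]; `k` values exceeding the feature
#'   count are dropped with a warning.
#' @return A `loo_search` object: `best_hp`, `predictions` (tibble of
#'   observed and cross-validated scores at the best cell), `grid_results`
#'   and `metrics` (see [prediction_metrics()]).
#' @export
loo_grid_search <- function(x, y, grid = hyperparam_grid()) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (n < 5) stop_invalid("leave-one-out search needs at least 5 subjects.")
  if (nrow(x) != n) stop_invalid("`x` and `y` disagree on subject count.")
  if (!inherits(grid, "hyperparam_grid")) stop_config("`grid` must be a hyperparam_grid.")
  kv <- grid$k_values[grid$k_values <= ncol(x)]
  if (!length(kv)) stop_config("all grid k values exceed the feature count.")
  if (length(kv) < length(grid$k_values)) {
    warn("dropped grid k values exceeding the feature count.")
  }
  cells <- tidyr::expand_grid(k_best = kv, l1_ratio = grid$l1_ratios) |>
    as.data.frame()
  alphas_desc <- sort(grid$alphas, decreasing = TRUE)
  n_alpha <- length(alphas_desc)
  # predictions: n x (cells x alphas)
  preds <- matrix(NA_real_, n, nrow(cells) * n_alpha)

  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    sc <- robust_scale_fit(xtr)
    xtr_s <- robust_scale_apply(xtr, sc)
    xte_s <- robust_scale_apply(x[i, , drop = FALSE], sc)
    ranked <- kbest_rank(xtr_s, ytr)
    for (ci in seq_len(nrow(cells))) {
      sel <- sort(ranked[seq_len(cells$k_best[ci])])
      xs <- xtr_s[, sel, drop = FALSE]
      xt <- xte_s[, sel, drop = FALSE]
      if (length(sel) == 1) {
        for (ai in seq_len(n_alpha)) {
          f <- enet_1d(xs[, 1], ytr, alphas_desc[ai], cells$l1_ratio[ci])
          preds[i, (ci - 1) * n_alpha + ai] <- f$b + f$w * xt[1, 1]
        }
      } else {
        # glmnet along a padded path for speed, then a short coordinate-
        # descent polish per alpha so fold models match fit_pipeline()
        path <- sort(unique(c(alphas_desc, max(alphas_desc) * c(16, 8, 4, 2))),
                     decreasing = TRUE)
        fit <- glmnet::glmnet(xs, ytr, family = "gaussian",
                              alpha = cells$l1_ratio[ci],
                              lambda = path, standardize = FALSE,
                              thresh = 1e-10, maxit = 1e6)
        w_path <- as.matrix(coef(fit, s = alphas_desc))
        for (ai in seq_len(n_alpha)) {
          pol <- enet_cd(xs, ytr, alphas_desc[ai], cells$l1_ratio[ci],
                         w_path[-1, ai], tol = 1e-7, max_pass = 200)
          preds[i, (ci - 1) * n_alpha + ai] <-
            pol$intercept + sum(xt[1, ] * pol$weights)
        }
      }
    }
  }

  res <- tidyr::expand_grid(
    cell = seq_len(nrow(cells)),
    alpha = alphas_desc
  )
  res$k_best <- cells$k_best[res$cell]
  res$l1_ratio <- cells$l1_ratio[res$cell]
  col_id <- (res$cell - 1) * n_alpha +
    match(res$alpha, alphas_desc)
  res$cv_mse <- colMeans((preds[, col_id, drop = FALSE] - y)^2)
  res <- dplyr::select(res, "k_best", "l1_ratio", "alpha", "cv_mse")
  ord <- order(res$cv_mse, res$k_best, -res$alpha, res$l1_ratio)
  best <- res[ord[1], ]
  best_col <- (which(cells$k_best == best$k_best &
                       cells$l1_ratio == best$l1_ratio)[1] - 1) * n_alpha +
    match(best$alpha, alphas_desc)
  y_cv <- preds[, best_col]
  structure(
    list(best_hp = pipeline_hp(best$k_best, best$l1_ratio, best$alpha),
         predictions = tibble(subject = seq_len(n), y = y, y_cv = y_cv),
         grid_results = as_tibble(res),
         metrics = prediction_metrics(y, y_cv)),
    class = "loo_search"
  )
}

#' @export
print.loo_search <- function(x, ...) {
  cat("Leave-one-out grid search\n")
  cat(sprintf("  best: K = %d, l1_ratio = %g, alpha = %g (CV MSE %.4f)\n",
              x$best_hp$k_best, x$best_hp$l1_ratio, x$best_hp$alpha,
              min(x$grid_results$cv_mse)))
  invisible(x)
}

#' @export
tidy.loo_search <- function(x, ...) x$grid_results

#' @export
glance.loo_search <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k_best = x$best_hp$k_best, l1_ratio = x$best_hp$l1_ratio,
           alpha = x$best_hp$alpha),
    x$metrics
  )
}

#' @export
augment.loo_search <- function(x, ...) x$predictions

# learning curve -------------------------------------------------------------

#' Learning curve at fixed hyperparameters
#'
#' For each training fraction, random subject subsets are fitted and
#' evaluated on the held-out remainder; increasing training error together
#' with decreasing test error indicates shrinking overfitting.
#'
#' @param x Subjects x features matrix.
#' @param y Numeric scores.
#' @param hp A [pipeline_hp()].
#' @param train_fractions Fractions of subjects used for training, in
#'   (0, 1]; at fraction 1 only the training error is defined.
#' @param n_repeats Random subsets per fraction.
#' @param seed Integer seed; results are reproducible given `seed`.
#' @return A `learning_curve` tibble: one row per (fraction, repeat) with
#'   `n_train`, `train_mse`, `test_mse`.
#' @export
learning_curve <- function(x, y, hp = pipeline_hp(),
                           train_fractions = seq(0.2, 1, by = 0.2),
                           n_repeats = 10, seed = 1) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (any(train_fractions <= 0 | train_fractions > 1)) {
    stop_config("`train_fractions` must lie in (0, 1].")
  }
  sizes <- unique(pmin(n, round(train_fractions * n)))
  if (min(sizes) < 5) stop_invalid("smallest training subset must have >= 5 subjects.")
  set.seed(seed)
  rows <- purrr::map(sizes, function(m) {
    purrr::map(seq_len(n_repeats), function(rep) {
      idx <- sample.int(n, m)
      fit <- fit_pipeline(x[idx, , drop = FALSE], y[idx], hp)
      train_mse <- mean((y[idx] - predict(fit, x[idx, , drop = FALSE]))^2)
      test_mse <- if (m < n - 1) {
        mean((y[-idx] - predict(fit, x[-idx, , drop = FALSE]))^2)
      } else {
        NA_real_
      }
      tibble(n_train = m, repeat_id = rep, train_mse = train_mse,
             test_mse = test_mse)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows, class = c("learning_curve", class(rows)), seed = seed)
}

#' @rdname learning_curve
#' @param object,... A `learning_curve` and unused arguments.
#' @export
autoplot.learning_curve <- function(object, ...) {
  summ <- object |>
    tidyr::pivot_longer(c("train_mse", "test_mse"),
                        names_to = "set", values_to = "mse") |>
    dplyr::filter(!is.na(.data$mse)) |>
    dplyr::group_by(.data$n_train, .data$set) |>
    dplyr::summarise(mean = mean(.data$mse), sd = sd(.data$mse), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_train, y = .data$mean,
                                     colour = .data$set, fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training subjects", y = "MSE") +
    ggplot2::theme_minimal()
}

# signature extraction and application ---------------------------------------

#' Extract the sparse signature from a fitted pipeline
#'
#' One entry per non-zero elastic-net weight, carrying the node pair, the
#' training median and IQR of the feature (so the signature is
#' self-contained for external application) and the intercept.
#'
#' @param fit A fitted `pain_pipeline`.
#' @param feature_map Optional tibble with columns `feature_index`,
#'   `label_i`, `label_j` mapping columns of the training matrix to node
#'   pairs; by default pair labels are parsed from feature names of the
#'   form `"<i>--<j>"`.
#' @param training_label,seed Provenance fields stored with the signature.
#' @return A `pain_signature`: a tibble of entries with attributes `mode`
#'   (`"full"`), `intercept`, `hyperparams` and `provenance`.
#' @export
extract_signature <- function(fit, feature_map = NULL,
                              training_label = "unnamed-training", seed = NA) {
  stopifnot(inherits(fit, "pain_pipeline"))
  nz <- which(fit$weights != 0)
  idx <- fit$selected[nz]
  if (is.null(feature_map)) {
    nm <- if (is.null(fit$feature_names)) paste0("f", idx) else fit$feature_names[idx]
    parts <- strsplit(nm, "--", fixed = TRUE)
    label_i <- vapply(parts, `[`, "", 1)
    label_j <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  } else {
    m <- match(idx, feature_map$feature_index)
    label_i <- feature_map$label_i[m]
    label_j <- feature_map$label_j[m]
  }
  entries <- tibble(
    feature_index = idx, label_i = label_i, label_j = label_j,
    weight = unname(fit$weights[nz]),
    median = unname(fit$center[idx]), iqr = unname(fit$scale[idx])
  )
  new_pain_signature(entries, mode = "full", intercept = fit$intercept,
                     hyperparams = fit$hp,
                     provenance = list(training_label = training_label,
                                       seed = seed,
                                       package = "rpnsig"))
}

new_pain_signature <- function(entries, mode, intercept = NULL,
                               hyperparams = NULL, provenance = list()) {
  stopifnot(mode %in% c("full", "weights_only"))
  if (anyDuplicated(entries$feature_index) && !all(is.na(entries$feature_index))) {
    stop_invalid("signature feature indices must be unique.")
  }
  if (any(entries$weight == 0)) stop_invalid("signature weights must be non-zero.")
  structure(as_tibble(entries),
            class = c("pain_signature", class(as_tibble(entries))),
            mode = mode, intercept = intercept, hyperparams = hyperparams,
            provenance = provenance)
}

#' @export
print.pain_signature <- function(x, ...) {
  cat(sprintf("Pain-sensitivity connectome signature (%s mode): %d connections\n",
              attr(x, "mode"), nrow(x)))
  NextMethod()
}

#' @export
tidy.pain_signature <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.pain_signature <- function(x, ...) {
  hp <- attr(x, "hyperparams")
  tibble(
    mode = attr(x, "mode"), n_connections = nrow(x),
    max_abs_weight = if (nrow(x)) max(abs(x$weight)) else NA_real_,
    intercept = attr(x, "intercept") %||% NA_real_,
    k_best = if (is.null(hp)) NA_integer_ else hp$k_best,
    l1_ratio = if (is.null(hp)) NA_real_ else hp$l1_ratio,
    alpha = if (is.null(hp)) NA_real_ else hp$alpha
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fetch the feature values a signature needs from various input shapes
signature_feature_values <- function(sig, x) {
  pairs_i <- sig$label_i; pairs_j <- sig$label_j
  if (inherits(x, "conn_features")) x <- devectorize(x)
  if (inherits(x, "conn_matrix") || (is.matrix(x) && isTRUE(all.equal(unname(nrow(x)), unname(ncol(x)))) &&
                                     !is.null(rownames(x)) && identical(rownames(x), colnames(x)))) {
    labs <- rownames(x)
    missing <- !(pairs_i %in% labs) | !(pairs_j %in% labs)
    if (any(missing)) {
      abort(paste0("input lacks signature node pairs: ",
                   paste(paste(pairs_i[missing], pairs_j[missing], sep = "--"),
                         collapse = ", ")),
            class = c("rpnsig_error_missing_feature", "rpnsig_error"))
    }
    vals <- matrix(unclass(x)[cbind(match(pairs_i, labs), match(pairs_j, labs))],
                   nrow = 1)
    rownames(vals) <- "subject"
    return(vals)
  }
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    rows <- lapply(x, function(m) signature_feature_values(sig, m))
    return(do.call(rbind, rows))
  }
  # subjects x features matrix with "<i>--<j>" column names
  xm <- as.matrix(x)
  key1 <- paste0(pairs_i, "--", pairs_j)
  key2 <- paste0(pairs_j, "--", pairs_i)
  col <- match(key1, colnames(xm))
  col[is.na(col)] <- match(key2, colnames(xm))[is.na(col)]
  if (any(is.na(col))) {
    abort(paste0("input lacks signature node pairs: ",
                 paste(key1[is.na(col)], collapse = ", ")),
          class = c("rpnsig_error_missing_feature", "rpnsig_error"))
  }
  xm[, col, drop = FALSE]
}

#' Apply a signature to new connectivity data
#'
#' Full-mode signatures reproduce the training pipeline exactly:
#' `score = intercept + sum_e w_e * (x_e - median_e) / iqr_e`. Weights-only
#' signatures (such as the published fixture, which prints no scaler
#' parameters) return the plain dot product `sum_e w_e * x_e`; such scores
#' are defined only up to an affine transformation and are flagged as such.
#'
#' @param sig A `pain_signature`.
#' @param x A `conn_matrix`, a list of them, a `conn_features` tibble, or a
#'   subjects x features matrix with `"<i>--<j>"` column names.
#' @return Tibble with columns `subject` and `prediction`; attribute
#'   `affine_relative` is TRUE for weights-only signatures.
#' @export
apply_signature <- function(sig, x) {
  stopifnot(inherits(sig, "pain_signature"))
  mode <- attr(sig, "mode")
  if (nrow(sig) == 0) {
    single_conn <- inherits(x, c("conn_matrix", "conn_features")) ||
      (is.matrix(x) && nrow(x) == ncol(x) && !is.null(rownames(x)) &&
         identical(rownames(x), colnames(x)))
    n <- if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) length(x)
         else if (single_conn) 1
         else nrow(as.matrix(x))
    score <- rep(attr(sig, "intercept") %||% 0, n)
    out <- tibble(subject = seq_len(n), prediction = score)
    return(structure(out, affine_relative = mode == "weights_only"))
  }
  vals <- signature_feature_values(sig, x)
  if (mode == "full") {
    scaled <- sweep(sweep(vals, 2, sig$median), 2, sig$iqr, "/")
    score <- as.numeric(scaled %*% sig$weight) + attr(sig, "intercept")
  } else {
    score <- as.numeric(vals %*% sig$weight)
  }
  out <- tibble(subject = seq_len(length(score)), prediction = score)
  structure(out, affine_relative = mode == "weights_only",
            n_connections_used = nrow(sig))
}

# metrics --------------------------------------------------------------------

#' Prediction performance metrics
#'
#' @param y Observed scores.
#' @param y_hat Predicted scores.
#' @return One-row tibble with `mse`, `mae`, `explained_variance`
#'   (`1 - Var(y - y_hat)/Var(y)`) and `pearson_r` (`NA` when the
#'   prediction is constant, in which case r is undefined).
#' @export
prediction_metrics <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop_invalid("`y` and `y_hat` differ in length.")
  if (length(y) < 3) stop_invalid("at least 3 observations are required.")
  r <- if (sd(y_hat) == 0) NA_real_ else cor(y, y_hat)
  tibble(
    mse = mean((y - y_hat)^2),
    mae = mean(abs(y - y_hat)),
    explained_variance = 1 - var(y - y_hat) / var(y),
    pearson_r = r
  )
}

#' Observed-vs-predicted scatter plot
#'
#' @param y Observed scores.
#' @param y_hat Predicted scores.
#' @return A ggplot object annotated with MAE and Pearson r.
#' @export
plot_predictions <- function(y, y_hat) {
  m <- prediction_metrics(y, y_hat)
  df <- tibble(y = y, y_hat = y_hat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$y_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_abline(slope = 1, intercept = c(-m$mae, m$mae),
                         linetype = 2, colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "observed pain sensitivity", y = "predicted",
      subtitle = sprintf("MAE = %.3f, r = %.2f", m$mae, m$pearson_r)
    ) +
    ggplot2::theme_minimal()
}
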