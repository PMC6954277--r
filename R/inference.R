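# Permutation and bootstrap inference: p-values for prediction metrics,
# bootstrap stability of signature weights, confound association tests.

#' Permutation p-values for prediction metrics
#'
#' Permutes the observed scores against the fixed predictions and asks how
#' often a permutation performs at least as well as the observed pairing:
#' lower MSE, higher explained variance, higher Pearson r respectively.
#' Add-one estimator: `p = (1 + n_as_good) / (n_perm + 1)`, so p never
#' reaches 0.
#'
#' This is the external-validation style test (predictions fixed). For
#' internal validation a full-refit mode that reruns the entire
#' cross-validated pipeline per permutation is available via
#' `refit = list(x = , grid = )`; it is orders of magnitude more expensive.
#'
#' @param y Observed scores.
#' @param y_hat Predicted scores.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param refit Optional list with elements `x` (feature matrix) and `grid`
#'   ([hyperparam_grid()]): per permutation the LOO pipeline is refitted on
#'   the permuted scores and its cross-validated predictions are scored.
#' @return One-row tibble with the observed metrics and `p_mse`,
#'   `p_explvar`, `p_r`, plus `n_perm` and `seed`.
#' @export
permutation_test_metrics <- function(y, y_hat, n_perm = 10000, seed = 1,
                                     refit = NULL) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop_invalid("`y` and `y_hat` differ in length.")
  if (length(y) < 5) stop_invalid("at least 5 paired observations required.")
  if (n_perm < 100) warn("fewer than 100 permutations gives a very coarse p-value.")
  obs <- prediction_metrics(y, y_hat)
  n <- length(y)
  set.seed(seed)
  if (is.null(refit)) {
    perm <- replicate(n_perm, sample(y))
    # vectorised metrics over the n x n_perm permutation matrix
    res <- perm - y_hat
    mse_p <- colMeans(res^2)
    ev_p <- 1 - apply(res, 2, var) / apply(perm, 2, var)
    r_p <- if (sd(y_hat) == 0) rep(NA_real_, n_perm) else as.vector(cor(y_hat, perm))
  } else {
    vals <- purrr::map(seq_len(n_perm), function(b) {
      yp <- sample(y)
      sr <- loo_grid_search(refit$x, yp, refit$grid)
      sr$metrics
    }) |> purrr::list_rbind()
    mse_p <- vals$mse; ev_p <- vals$explained_variance; r_p <- vals$pearson_r
  }
  p_of <- function(stat_perm, better) {
    (1 + sum(better(stat_perm), na.rm = TRUE)) / (n_perm + 1)
  }
  dplyr::bind_cols(
    obs,
    tibble(
      p_mse = p_of(mse_p, function(s) s <= obs$mse),
      p_explvar = p_of(ev_p, function(s) s >= obs$explained_variance),
      p_r = if (is.na(obs$pearson_r)) NA_real_ else p_of(r_p, function(s) s >= obs$pearson_r),
      n_perm = n_perm, seed = seed
    )
  )
}

#' Bootstrap inference on signature weights
#'
#' Draws `B` bootstrap samples of (subject, score) pairs with replacement,
#' refits the full pipeline at fixed hyperparameters on each, and
#' summarises every feature conditional on its K-best selection within a
#' sample: the selection frequency, a percentile 95% CI of the selected
#' weights, and a two-sided sign-based p-value
#' `p = 2 * min(#w <= 0, #w >= 0) / n_selected`, floored at
#' `1 / n_selected`. Features never selected report `NA` intervals.
#'
#' @param x Subjects x features matrix.
#' @param y Numeric scores.
#' @param hp A [pipeline_hp()].
#' @param B Number of bootstrap samples (default 10000).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval.
#' @return A `bootstrap_summary` tibble: one row per feature ever selected,
#'   with `feature_index`, `term`, `selection_frequency`, `ci_low`,
#'   `ci_high`, `p`, `mean_weight`; `B` and `seed` stored as attributes.
#' @export
bootstrap_signature <- function(x, y, hp = pipeline_hp(), B = 10000, seed = 1,
                                conf_level = 0.95) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop_invalid("bootstrap inference needs at least 10 subjects.")
  if (B < 100) warn("fewer than 100 bootstrap samples gives unstable summaries.")
  set.seed(seed)
  p <- ncol(x)
  sel_count <- integer(p)
  weights <- vector("list", p)  # grown lazily per feature
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (sd(yb) == 0) next
    fit <- fit_pipeline(x[idx, , drop = FALSE], yb, hp)
    sel_count[fit$selected] <- sel_count[fit$selected] + 1L
    for (k in seq_along(fit$selected)) {
      j <- fit$selected[k]
      weights[[j]] <- c(weights[[j]], fit$weights[k])
    }
  }
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ever <- which(sel_count > 0)
  rows <- purrr::map(ever, function(j) {
    w <- weights[[j]]
    ns <- length(w)
    ci <- quantile(w, probs, names = FALSE)
    pval <- max(2 * min(sum(w <= 0), sum(w >= 0)) / ns, 1 / ns)
    tibble(feature_index = j,
           term = colnames(x)[j] %||% paste0("f", j),
           selection_frequency = ns / B,
           ci_low = ci[1], ci_high = ci[2],
           p = min(pval, 1), mean_weight = mean(w))
  }) |> purrr::list_rbind()
  rows <- dplyr::arrange(rows, dplyr::desc(.data$selection_frequency))
  structure(rows, class = c("bootstrap_summary", class(rows)),
            B = B, seed = seed, conf_level = conf_level)
}

#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble(B = attr(x, "B"), seed = attr(x, "seed"),
         conf_level = attr(x, "conf_level"),
         n_features_selected = nrow(x))
}

#' Permutation-based confound association
#'
#' Ordinary least squares of the predicted score on one covariate
#' (dummy-coded when categorical), with significance assessed by permuting
#' the covariate: `p = (1 + #{R2_perm >= R2_obs}) / (n_perm + 1)`. Pairs
#' with missing values are dropped and the n actually used is reported.
#'
#' @param score Per-subject predicted pain-sensitivity scores.
#' @param covariate Numeric or factor/character covariate of equal length.
#' @param type `"continuous"` or `"categorical"`; guessed from the
#'   covariate class by default (character/factor/logical -> categorical).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble with `r_squared`, `p`, `n`, `type`, `n_perm`,
#'   `seed`.
#' @export
confound_association <- function(score, covariate,
                                 type = NULL, n_perm = 10000, seed = 1) {
  score <- as.numeric(score)
  if (length(score) != length(covariate)) {
    stop_invalid("`score` and `covariate` differ in length.")
  }
  if (is.null(type)) {
    type <- if (is.character(covariate) || is.factor(covariate) ||
                is.logical(covariate)) "categorical" else "continuous"
  }
  type <- match.arg(type, c("continuous", "categorical"))
  keep <- !is.na(score) & !is.na(covariate)
  s <- score[keep]
  v <- covariate[keep]
  n <- length(s)
  if (n < 5) stop_invalid("fewer than 5 complete pairs.")

  if (type == "continuous") {
    v <- as.numeric(v)
    if (sd(v) == 0) {
      abort("covariate is constant.", class = c("rpnsig_error_degenerate_covariate", "rpnsig_error"))
    }
    r2 <- function(vv) cor(s, vv)^2
  } else {
    v <- factor(v)
    if (nlevels(v) < 2) {
      abort("covariate is constant.", class = c("rpnsig_error_degenerate_covariate", "rpnsig_error"))
    }
    sst <- sum((s - mean(s))^2)
    r2 <- function(vv) {
      gm <- tapply(s, vv, mean)
      1 - sum((s - gm[vv])^2) / sst
    }
  }
  obs <- r2(v)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) r2(sample(v)), numeric(1))
  tibble(
    r_squared = unname(obs),
    p = (1 + sum(perm >= obs)) / (n_perm + 1),
    n = n, type = type, n_perm = n_perm, seed = seed
  )
}

#' Confound table across several covariates
#'
#' Convenience wrapper running [confound_association()] for every column
#' of a covariate table.
#'
#' @param score Predicted scores.
#' @param covariates Data frame of covariates (one test per column).
#' @param n_perm,seed Passed to [confound_association()].
#' @return Tibble with one row per covariate.
#' @export
confound_table <- function(score, covariates, n_perm = 10000, seed = 1) {
  stopifnot(is.data.frame(covariates))
  purrr::imap(covariates, function(v, nm) {
    dplyr::mutate(
      confound_association(score, v, n_perm = n_perm, seed = seed),
      covariate = nm, .before = 1
    )
  }) |> purrr::list_rbind()
}
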