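# Partial-correlation connectome estimation and the upper-triangle
# feature space.

new_conn_matrix <- function(m, labels, modules = NULL, estimator = "unknown") {
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("conn_matrix", class(m)),
            modules = modules, estimator = estimator)
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("Partial-correlation matrix: %d x %d nodes (estimator: %s)\n",
              nrow(x), ncol(x), attr(x, "estimator")))
  invisible(x)
}

#' Partial-correlation connectivity matrix
#'
#' Estimates the partial correlation between every pair of nodes from the
#' precision matrix `Theta = solve(Sigma)`:
#' `pcor_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`. Partial rather than
#' marginal correlations suppress indirect connectivity. The covariance is
#' the Ledoit-Wolf shrinkage estimate by default, which stays invertible in
#' the frames < nodes regime typical for large parcellations; the plain
#' empirical covariance is available for oracle comparisons. The diagonal
#' is set to 0 by convention.
#'
#' @param ts A [regional_timeseries()] object or a frames x nodes matrix.
#' @param estimator `"shrinkage"` (default, [ledoit_wolf_cov()]) or
#'   `"empirical"`.
#' @return A `conn_matrix`: symmetric nodes x nodes matrix with node labels
#'   as dimnames and attributes `modules` and `estimator`.
#' @export
partial_correlation <- function(ts, estimator = c("shrinkage", "empirical")) {
  estimator <- match.arg(estimator)
  if (inherits(ts, "regional_ts")) {
    x <- ts$signal; labels <- ts$labels; modules <- ts$modules
  } else {
    x <- as.matrix(ts)
    labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("node_", seq_len(ncol(x)))
    modules <- NULL
  }
  if (nrow(x) <= 3) stop_invalid("need more than 3 frames.")
  if (ncol(x) < 2) stop_invalid("need at least 2 nodes.")
  check_finite(x, "ts")

  sigma <- if (estimator == "shrinkage") {
    ledoit_wolf_cov(x)
  } else {
    stats::cov(x)
  }
  theta <- tryCatch(
    solve(sigma),
    error = function(e) {
      abort(paste0("covariance matrix is singular (frames <= nodes?); ",
                   "use estimator = \"shrinkage\"."),
            class = c("rpnsig_error_singular", "rpnsig_error"))
    }
  )
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  pc <- (pc + t(pc)) / 2
  diag(pc) <- 0
  new_conn_matrix(pc, labels, modules = modules, estimator = estimator)
}

# feature index map ---------------------------------------------------------

#' Upper-triangle feature index map
#'
#' Row-major traversal of node pairs `i < j` for an `n`-node network.
#' With 0-based node indices the (0-based) feature index of pair `(i, j)`
#' is `i*(2n - i - 1)/2 + (j - i - 1)`; the returned tibble uses 1-based
#' indices throughout, consistent with that ordering.
#'
#' @param n Number of nodes.
#' @return Tibble with columns `feature_index`, `node_i`, `node_j`
#'   (`node_i < node_j`), one row per pair, `n*(n-1)/2` rows.
#' @export
feature_index_map <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) seq.int(k + 1, n)),
              use.names = FALSE)
  tibble(feature_index = seq_along(i), node_i = i, node_j = j)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Flattens a symmetric matrix to the feature vector used for predictive
#' modelling: pairs `i < j` in row-major order over the fixed node order
#' (atlas regions in ascending index, global grey-matter node last). A
#' 123-node matrix yields 7503 features.
#'
#' @param conn A `conn_matrix` (or symmetric labelled matrix).
#' @return A `conn_features` tibble with columns `feature_index`, `node_i`,
#'   `node_j`, `label_i`, `label_j`, `value`; node count kept in attribute
#'   `n_nodes`.
#' @export
vectorize_upper <- function(conn) {
  m <- unclass(conn)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_invalid("`conn` must be a square matrix.")
  if (max(abs(m - t(m))) > 1e-10) stop_invalid("`conn` must be symmetric.")
  n <- nrow(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  map <- feature_index_map(n)
  vals <- t(m)[lower.tri(m)]  # row-major upper triangle
  out <- dplyr::mutate(map,
                       label_i = labels[.data$node_i],
                       label_j = labels[.data$node_j],
                       value = vals)
  structure(out, class = c("conn_features", class(out)),
            n_nodes = n, labels = labels)
}

#' Rebuild a connectivity matrix from its feature vector
#'
#' Inverse of [vectorize_upper()] (up to the zero diagonal).
#'
#' @param features A `conn_features` tibble, or a numeric vector of length
#'   `n*(n-1)/2` in row-major upper-triangle order.
#' @param labels Node labels (required for plain numeric input).
#' @return A `conn_matrix`.
#' @export
devectorize <- function(features, labels = NULL) {
  if (inherits(features, "conn_features")) {
    labels <- attr(features, "labels")
    vals <- features$value
  } else {
    vals <- as.numeric(features)
  }
  if (is.null(labels)) stop_invalid("`labels` required when `features` is a bare vector.")
  n <- length(labels)
  if (length(vals) != n * (n - 1) / 2) {
    stop_invalid(sprintf("expected %d feature values for %d nodes, got %d.",
                         n * (n - 1) / 2, n, length(vals)))
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vals  # fills t(m)'s row-major upper triangle
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  new_conn_matrix(m, labels, estimator = "devectorized")
}

#' Reorder a connectivity matrix by large-scale modules
#'
#' Permutes nodes so that nodes sharing a module (large-scale network)
#' label are contiguous, with a stable within-module order. Mainly for
#' visualisation; the feature space always uses the original order.
#'
#' @param conn A `conn_matrix` with a `modules` attribute, or `modules`
#'   given explicitly.
#' @param modules Optional character vector of module labels per node.
#' @return The permuted `conn_matrix` (attribute `permutation` holds the
#'   applied node order).
#' @export
order_by_modules <- function(conn, modules = attr(conn, "modules")) {
  if (is.null(modules)) stop_invalid("module labels are required.")
  if (length(modules) != nrow(conn)) {
    stop_invalid("`modules` length must equal the node count.")
  }
  ord <- order(factor(modules, levels = unique(modules)))
  out <- unclass(conn)[ord, ord, drop = FALSE]
  out <- new_conn_matrix(out, rownames(conn)[ord],
                         modules = modules[ord],
                         estimator = attr(conn, "estimator"))
  attr(out, "permutation") <- ord
  out
}

#' Node-wise predictive strength
#'
#' Sums the signature weights of all connections incident to each node,
#' giving the per-region contribution map of a sparse connectome signature.
#'
#' @param signature A `pain_signature` (see [extract_signature()] or
#'   [rpn_signature()]).
#' @param nodes Optional character vector of node labels to report
#'   (absent-from-signature nodes get strength 0); defaults to the nodes
#'   appearing in the signature.
#' @return Tibble with columns `node` and `strength`, sorted by decreasing
#'   `abs(strength)`.
#' @export
node_predictive_strength <- function(signature, nodes = NULL) {
  entries <- as_tibble(signature)
  if (is.null(nodes)) nodes <- unique(c(entries$label_i, entries$label_j))
  strength <- setNames(numeric(length(nodes)), nodes)
  if (nrow(entries)) {
    for (k in seq_len(nrow(entries))) {
      w <- entries$weight[k]
      for (lab in c(entries$label_i[k], entries$label_j[k])) {
        if (lab %in% nodes) strength[lab] <- strength[lab] + w
      }
    }
  }
  tibble(node = names(strength), strength = unname(strength)) |>
    dplyr::arrange(dplyr::desc(abs(.data$strength)))
}

#' Heatmap of a connectivity matrix
#'
#' @param conn A `conn_matrix`.
#' @param order_modules Reorder nodes by module labels first (if present).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn, order_modules = FALSE) {
  if (order_modules && !is.null(attr(conn, "modules"))) {
    conn <- order_by_modules(conn)
  }
  n <- nrow(conn)
  labels <- rownames(conn)
  df <- tibble(
    i = rep(seq_len(n), each = n),
    j = rep(seq_len(n), times = n),
    value = as.vector(t(unclass(conn)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r") +
    ggplot2::theme_minimal()
}
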