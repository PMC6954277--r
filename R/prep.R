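# Regional-timeseries cleaning: CompCor components, nuisance regression,
# bandpass filtering and frame censoring.

#' Regional timeseries container
#'
#' Bundles a frames x nodes signal matrix with node labels, large-scale
#' module (network) labels, the repetition time, and the original frame
#' indices (updated when frames are censored). When a global grey-matter
#' node is present it is by convention the last node.
#'
#' @param signal Numeric frames x nodes matrix.
#' @param labels Character node labels (default taken from column names).
#' @param tr Repetition time in seconds.
#' @param modules Optional character vector of module labels, one per node.
#' @return A `regional_ts` object.
#' @export
regional_timeseries <- function(signal, labels = colnames(signal), tr,
                                modules = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  check_finite(signal, "signal")
  if (is.null(labels)) labels <- paste0("node_", seq_len(ncol(signal)))
  if (length(labels) != ncol(signal)) {
    stop_invalid("`labels` length must equal the number of nodes.")
  }
  if (!is.null(modules) && length(modules) != ncol(signal)) {
    stop_invalid("`modules` length must equal the number of nodes.")
  }
  if (!is.numeric(tr) || tr <= 0) stop_config("`tr` must be a positive number of seconds.")
  colnames(signal) <- labels
  structure(
    list(signal = signal, labels = labels, modules = modules, tr = tr,
         frames = seq_len(nrow(signal)), steps = character(0)),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("Regional timeseries: %d frames x %d nodes, TR = %g s\n",
              nrow(x$signal), ncol(x$signal), x$tr))
  if (length(x$steps)) cat("  cleaning steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.regional_ts <- function(x) dim(x$signal)

#' @export
as_tibble.regional_ts <- function(x, ...) {
  out <- as_tibble(x$signal)
  out <- dplyr::mutate(out, frame = x$frames, .before = 1)
  out
}

record_step <- function(ts, step) {
  ts$steps <- c(ts$steps, step)
  ts
}

#' CompCor nuisance components
#'
#' Extracts the leading principal components of a noise-region signal
#' matrix (e.g. eroded white matter and ventricle signals). Columns of the
#' input are demeaned; components are ordered by explained variance, have
#' unit norm, and their sign is fixed so that the largest-magnitude loading
#' of each component is positive.
#'
#' @param noise_signals Numeric frames x q matrix of noise-region signals.
#' @param n_components Number of components to return (default 6).
#' @return A frames x `n_components` matrix with attribute
#'   `explained_variance` (per-component variance ratios).
#' @export
compcor_components <- function(noise_signals, n_components = 6) {
  x <- as.matrix(noise_signals)
  storage.mode(x) <- "double"
  check_finite(x, "noise_signals")
  if (ncol(x) < n_components) {
    stop_invalid("fewer noise signals than requested components.")
  }
  if (nrow(x) <= n_components) {
    stop_invalid("need more frames than requested components.")
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_components, nv = n_components)
  u <- sv$u
  for (j in seq_len(n_components)) {
    load_j <- sv$v[, j]
    if (load_j[which.max(abs(load_j))] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("compcor_", seq_len(n_components))
  structure(u, explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}

#' Assemble a nuisance regressor set
#'
#' Binds named nuisance blocks (CompCor components, Friston-24 expansion,
#' any extra regressors) into one design block and validates frame counts.
#'
#' @param ... Named numeric matrices/vectors with one row per frame.
#' @return A frames x q matrix with block-prefixed column names.
#' @export
nuisance_set <- function(...) {
  blocks <- list(...)
  if (!length(blocks)) stop_invalid("at least one nuisance block is required.")
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop_invalid("all nuisance blocks must be named.")
  }
  mats <- lapply(names(blocks), function(nm) {
    b <- as.matrix(blocks[[nm]])
    if (is.null(colnames(b))) colnames(b) <- paste0(nm, "_", seq_len(ncol(b)))
    b
  })
  n <- vapply(mats, nrow, integer(1))
  if (length(unique(n)) != 1) stop_invalid("nuisance blocks differ in frame count.")
  out <- do.call(cbind, mats)
  if (any(apply(out, 2, function(v) all(v == 0)))) {
    warn("nuisance set contains all-zero columns.")
  }
  out
}

#' Nuisance regression
#'
#' Removes nuisance signals from every node by ordinary least squares on
#' `[intercept, nuisance, linear trend]`, returning the residuals. With a
#' rank-deficient design a warning is emitted and the minimum-norm
#' (pseudo-inverse) solution is used; the residuals are identical for any
#' solution of the normal equations.
#'
#' @param ts A [regional_timeseries()] object.
#' @param nuisance Frames x q nuisance matrix (see [nuisance_set()]).
#' @param add_linear_trend Include a linear trend regressor (default TRUE).
#' @return The input `regional_ts` with residual signals.
#' @export
nuisance_regression <- function(ts, nuisance, add_linear_trend = TRUE) {
  stopifnot(inherits(ts, "regional_ts"))
  x <- as.matrix(nuisance)
  n <- nrow(ts$signal)
  if (nrow(x) != n) stop_invalid("nuisance frame count does not match the timeseries.")
  design <- cbind(intercept = rep(1, n), x)
  if (add_linear_trend) design <- cbind(design, trend = seq_len(n) - (n + 1) / 2)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    warn("rank-deficient nuisance design; using the pseudo-inverse solution.")
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], ts$signal) / sv$d[pos])
    resid <- ts$signal - design %*% beta
  } else {
    resid <- qr.resid(qr_d, ts$signal)
  }
  colnames(resid) <- ts$labels
  ts$signal <- resid
  record_step(ts, "nuisance_regression")
}

#' Fourier-domain bandpass filter
#'
#' Ideal (brick-wall) bandpass applied per node in the discrete Fourier
#' domain: frequency bins inside `[low, high]` are retained, everything
#' else -- including the DC component -- is zeroed. This mirrors the
#' behaviour of the frequency-domain filters common in fMRI pipelines; a
#' zero-phase 4th-order Butterworth alternative is available via
#' `method = "butterworth"`.
#'
#' @param ts A [regional_timeseries()] object (its `tr` sets the sampling).
#' @param low,high Band edges in Hz (defaults 0.008 and 0.08).
#' @param method `"fourier"` (default) or `"butterworth"`.
#' @return The filtered `regional_ts`.
#' @export
bandpass <- function(ts, low = 0.008, high = 0.08,
                     method = c("fourier", "butterworth")) {
  stopifnot(inherits(ts, "regional_ts"))
  method <- match.arg(method)
  nyq <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stop_config(sprintf(
      "band edges must satisfy 0 < low < high < Nyquist (= %.4f Hz).", nyq))
  }
  n <- nrow(ts$signal)
  if (method == "fourier") {
    freq <- seq(0, n - 1) / (n * ts$tr)
    freq <- pmin(freq, 1 / ts$tr - freq)  # fold to [0, Nyquist]
    keep <- freq >= low & freq <= high
    f <- stats::mvfft(ts$signal)
    f[!keep, ] <- 0
    filtered <- Re(stats::mvfft(f, inverse = TRUE)) / n
  } else {
    bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
    filtered <- apply(ts$signal, 2, function(v) {
      signal::filtfilt(bf, v - mean(v))
    })
  }
  colnames(filtered) <- ts$labels
  ts$signal <- filtered
  record_step(ts, sprintf("bandpass[%g-%g Hz,%s]", low, high, method))
}

#' Apply a censoring mask to a timeseries
#'
#' Drops scrubbed frames (in order) and records the surviving original
#' frame indices in the `frames` field.
#'
#' @param ts A [regional_timeseries()] object.
#' @param mask A [censor_mask()] (or logical vector, TRUE = retain).
#' @param min_frames Minimum number of retained frames (default 50); fewer
#'   raises a too-few-frames error.
#' @return The censored `regional_ts`.
#' @export
apply_censoring <- function(ts, mask, min_frames = 50) {
  stopifnot(inherits(ts, "regional_ts"))
  retain <- if (inherits(mask, "censor_mask")) mask$retain else as.logical(mask)
  if (length(retain) != nrow(ts$signal)) {
    stop_invalid("mask length must equal the number of frames.")
  }
  if (sum(retain) < min_frames) {
    abort(sprintf("only %d frames retained; at least %d required.",
                  sum(retain), min_frames),
          class = c("rpnsig_error_too_few_frames", "rpnsig_error"))
  }
  ts$signal <- ts$signal[retain, , drop = FALSE]
  ts$frames <- ts$frames[retain]
  record_step(ts, "apply_censoring")
}

#' Standard cleaning pipeline for one subject
#'
#' Fixed order: nuisance regression (CompCor + Friston-24 + linear trend),
#' bandpass filtering, then censoring -- the conventional sequence for
#' connectivity analysis. Each step is logged in the `steps` field.
#'
#' @param ts A [regional_timeseries()] object.
#' @param motion Motion-parameter table (see [framewise_displacement()]).
#' @param noise_signals Noise-region signal matrix for CompCor.
#' @param fd_threshold Scrubbing threshold in mm.
#' @param low,high Bandpass edges in Hz.
#' @param min_frames Minimum retained frames after censoring.
#' @return A list with elements `ts` (cleaned series), `fd`, `mask` and
#'   `exclusion` (the subject-level decision tibble).
#' @export
clean_timeseries <- function(ts, motion, noise_signals,
                             fd_threshold = 0.15, low = 0.008, high = 0.08,
                             min_frames = 50) {
  fd <- framewise_displacement(motion)
  mask <- censor_mask(fd, threshold = fd_threshold)
  nuis <- nuisance_set(
    compcor = compcor_components(noise_signals),
    friston24 = friston24(motion)
  )
  out <- ts |>
    nuisance_regression(nuis) |>
    bandpass(low = low, high = high) |>
    apply_censoring(mask, min_frames = min_frames)
  list(ts = out, fd = fd, mask = mask,
       exclusion = subject_motion_exclusion(fd, mask))
}
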