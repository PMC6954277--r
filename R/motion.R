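# Head-motion quality control: framewise displacement, the Friston-24
# nuisance expansion, frame censoring and subject-level exclusion.

.motion_cols <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")

# Coerce a motion-parameter table to the canonical frames x 6 matrix:
# rotations (radians) first, translations (mm) second. `col_order` lets
# callers declare a translation-first dialect.
as_motion_matrix <- function(motion, col_order = c("rot_first", "trans_first")) {
  col_order <- match.arg(col_order)
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop_invalid("motion parameters must have exactly 6 columns.")
  if (nrow(m) < 2) stop_invalid("at least 2 frames of motion parameters required.")
  check_finite(m, "motion")
  storage.mode(m) <- "double"
  if (col_order == "trans_first") m <- m[, c(4:6, 1:3), drop = FALSE]
  colnames(m) <- .motion_cols
  m
}

#' Power framewise displacement
#'
#' Summarises rigid-body head motion per frame as
#' `FD_t = sum(|delta trans|) + radius * sum(|delta rot|)`, with backward
#' differences and rotations converted to arc length on a sphere
#' (default radius 50 mm). The first frame has no predecessor and is
#' assigned FD = 0 so that the series aligns with the frames.
#'
#' @param motion Data frame or matrix of 6 motion parameters per frame:
#'   3 rotations in radians then 3 translations in mm (see `col_order`).
#' @param radius Sphere radius in mm used for the rotation conversion.
#' @param col_order `"rot_first"` (default) or `"trans_first"`.
#' @return An `fd_series` tibble with columns `frame` and `fd` (mm), with
#'   summaries `mean_fd`, `median_fd`, `max_fd` and `radius` as attributes
#'   (retrieved tidily via `glance()`).
#' @export
framewise_displacement <- function(motion, radius = 50,
                                   col_order = c("rot_first", "trans_first")) {
  m <- as_motion_matrix(motion, col_order)
  d <- abs(diff(m))
  fd <- c(0, radius * rowSums(d[, 1:3, drop = FALSE]) +
            rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble(frame = seq_len(nrow(m)), fd = fd)
  structure(out,
            class = c("fd_series", class(out)),
            mean_fd = mean(fd), median_fd = median(fd), max_fd = max(fd),
            radius = radius)
}

#' @export
glance.fd_series <- function(x, ...) {
  tibble(mean_fd = attr(x, "mean_fd"), median_fd = attr(x, "median_fd"),
         max_fd = attr(x, "max_fd"), radius = attr(x, "radius"),
         n_frames = nrow(x))
}

#' Friston-24 motion nuisance expansion
#'
#' Expands the 6 rigid-body parameters into 24 nuisance regressors:
#' the parameters, their squares, their backward-difference derivatives
#' (first row 0) and the squared derivatives, in that block order.
#'
#' @inheritParams framewise_displacement
#' @return A frames x 24 numeric matrix with columns
#'   `<p>`, `<p>_sq`, `<p>_d`, `<p>_dsq` for each parameter `<p>`.
#' @export
friston24 <- function(motion, col_order = c("rot_first", "trans_first")) {
  m <- as_motion_matrix(motion, col_order)
  d <- rbind(0, diff(m))
  out <- cbind(m, m^2, d, d^2)
  colnames(out) <- c(.motion_cols,
                     paste0(.motion_cols, "_sq"),
                     paste0(.motion_cols, "_d"),
                     paste0(.motion_cols, "_dsq"))
  out
}

#' Frame censoring mask from framewise displacement
#'
#' Frames whose FD strictly exceeds the threshold are marked for scrubbing;
#' a frame with FD exactly at the threshold is retained.
#'
#' @param fd An `fd_series` from [framewise_displacement()] (or a numeric
#'   FD vector).
#' @param threshold Scrubbing threshold in mm (default 0.15).
#' @return A `censor_mask` tibble with columns `frame` and `retain`;
#'   attribute `scrub_fraction` gives the censored fraction.
#' @export
censor_mask <- function(fd, threshold = 0.15) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_config("`threshold` must be positive (mm).")
  }
  v <- if (inherits(fd, "fd_series")) fd$fd else as.numeric(fd)
  retain <- v <= threshold
  out <- tibble(frame = seq_along(v), retain = retain)
  structure(out,
            class = c("censor_mask", class(out)),
            scrub_fraction = mean(!retain), threshold = threshold)
}

#' @export
glance.censor_mask <- function(x, ...) {
  tibble(n_frames = nrow(x), n_scrubbed = sum(!x$retain),
         scrub_fraction = attr(x, "scrub_fraction"),
         threshold = attr(x, "threshold"))
}

#' Subject-level motion exclusion decision
#'
#' A subject is excluded when the mean FD (computed over all frames, before
#' scrubbing) exceeds `mean_fd_limit`, or when more than `scrub_limit` of
#' frames were scrubbed. Both reasons are reported.
#'
#' @param fd An `fd_series` from [framewise_displacement()].
#' @param mask A `censor_mask` derived from the same series.
#' @param mean_fd_limit Mean-FD exclusion limit in mm (default 0.15).
#' @param scrub_limit Scrubbed-fraction exclusion limit (default 0.30).
#' @return A one-row tibble with `mean_fd`, `scrub_fraction`, logical
#'   reasons `fail_mean_fd` / `fail_scrub`, and `decision`
#'   (`"keep"`/`"exclude"`).
#' @export
subject_motion_exclusion <- function(fd, mask, mean_fd_limit = 0.15,
                                     scrub_limit = 0.30) {
  stopifnot(inherits(fd, "fd_series"), inherits(mask, "censor_mask"))
  if (nrow(fd) != nrow(mask)) {
    stop_invalid("`mask` must be derived from `fd` (frame counts differ).")
  }
  mfd <- attr(fd, "mean_fd")
  sfrac <- attr(mask, "scrub_fraction")
  fail_mean <- mfd > mean_fd_limit
  fail_scrub <- sfrac > scrub_limit
  tibble(
    mean_fd = mfd, scrub_fraction = sfrac,
    fail_mean_fd = fail_mean, fail_scrub = fail_scrub,
    decision = if (fail_mean || fail_scrub) "exclude" else "keep"
  )
}

#' @rdname framewise_displacement
#' @param object,x An `fd_series`.
#' @param threshold Censoring threshold drawn on the plot.
#' @param ... Unused.
#' @export
autoplot.fd_series <- function(object, threshold = 0.15, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$fd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = "frame", y = "framewise displacement (mm)") +
    ggplot2::theme_minimal()
}
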