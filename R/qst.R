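# Quantitative sensory testing: single-modality thresholds and the
# composite pain-sensitivity score.

#' Thermal pain threshold from repeated method-of-limits trials
#'
#' The first trial is treated as a test stimulus and discarded; the threshold
#' is the arithmetic mean of the remaining trial temperatures. The standard
#' protocol uses 6 repetitions (5 retained) but any number of trials >= 2 is
#' accepted.
#'
#' @param trial_temperatures Numeric vector of threshold temperatures
#'   (degrees Celsius), in acquisition order.
#' @return A single temperature in degrees Celsius.
#' @examples
#' thermal_pain_threshold(c(44.0, 44.6, 44.2, 44.8, 44.4, 44.5))
#' @export
thermal_pain_threshold <- function(trial_temperatures) {
  x <- as.numeric(trial_temperatures)
  if (length(x) < 2) {
    stop_invalid("at least 2 trials are required (the first is discarded).")
  }
  check_finite(x, "trial_temperatures")
  mean(x[-1])
}

#' Mechanical pain threshold from staircase runs
#'
#' Computes the log-transformed geometric mean of the per-run threshold
#' forces, i.e. the mean of `log10(force)`, which is the scale on which
#' mechanical thresholds enter the composite score.
#'
#' @param run_forces Numeric vector of per-run threshold forces in mN
#'   (strictly positive). The standard protocol yields 10 values
#'   (5 ascending + 5 descending staircase runs).
#' @return Threshold on the log10 mN scale.
#' @examples
#' mechanical_pain_threshold(c(8, 16, 32, 64, 128, 8, 16, 32, 64, 128))
#' @export
mechanical_pain_threshold <- function(run_forces) {
  x <- as.numeric(run_forces)
  if (length(x) < 1) stop_invalid("at least one staircase run is required.")
  check_finite(x, "run_forces")
  if (any(x <= 0)) stop_invalid("all forces must be strictly positive (mN).")
  mean(log10(x))
}

#' T50: temperature producing a heat-pain rating of 50/100
#'
#' Fits a second-order polynomial `rating = a*T^2 + b*T + c` to
#' temperature-rating pairs by least squares and returns the root at
#' rating = 50 that lies within the stimulated temperature range. If both
#' roots fall in range the larger (ascending-branch) root is returned.
#'
#' @param pairs Data frame with columns `temperature` (degrees Celsius) and
#'   `rating` (0-100 visual analogue scale).
#' @return The T50 temperature in degrees Celsius.
#' @export
t50_from_ratings <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("temperature", "rating") %in% names(pairs))) {
    stop_invalid("`pairs` needs columns `temperature` and `rating`.")
  }
  tt <- as.numeric(pairs$temperature)
  rr <- as.numeric(pairs$rating)
  if (length(tt) < 3) stop_invalid("at least 3 temperature-rating pairs required.")
  check_finite(tt, "temperature")
  check_finite(rr, "rating")
  if (any(rr < 0 | rr > 100)) stop_invalid("ratings must lie in [0, 100].")

  fit <- lm(rr ~ tt + I(tt^2))
  cc <- coef(fit)
  a <- unname(cc[3]); b <- unname(cc[2]); c0 <- unname(cc[1]) - 50
  rng <- range(tt)
  span <- diff(rng)
  tol <- 1e-8 * max(1, max(abs(rr)))

  roots <- if (abs(a) * span^2 < tol) {
    if (abs(b) * span < tol) {
      abort("degenerate polynomial fit: rating does not vary with temperature.",
            class = c("rpnsig_error_degenerate_fit", "rpnsig_error"))
    }
    -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  eps <- 1e-6 * max(1, span)
  in_range <- roots[roots >= rng[1] - eps & roots <= rng[2] + eps]
  if (length(in_range) == 0) {
    abort("no rating-50 crossing within the stimulated temperature range.",
          class = c("rpnsig_error_no_solution", "rpnsig_error"))
  }
  max(in_range)
}

# reference statistics and normative bounds --------------------------------

.qst_modalities <- c("hpt", "cpt", "mpt")
# modalities whose raw scale runs opposite to sensitivity: low HPT and low
# MPT force mean high sensitivity, so their z-scores are multiplied by -1
.qst_inverted <- c("hpt", "mpt")

#' Reference statistics for cross-study z-scoring
#'
#' The composite score z-transforms each threshold against a fixed reference
#' population (the training cohort), so that scores from different cohorts
#' share one scale.
#'
#' @param hpt_mu,hpt_sd,cpt_mu,cpt_sd,mpt_mu,mpt_sd Reference mean and
#'   standard deviation per modality (HPT/CPT in degrees Celsius, MPT in
#'   log10 mN). All sds must be positive.
#' @param source Free-text label recording where the statistics come from.
#' @return A `qst_reference` object (named list).
#' @export
qst_reference <- function(hpt_mu, hpt_sd, cpt_mu, cpt_sd, mpt_mu, mpt_sd,
                          source = "unspecified") {
  sds <- c(hpt_sd, cpt_sd, mpt_sd)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop_config("all reference standard deviations must be positive.")
  }
  structure(
    list(hpt_mu = hpt_mu, hpt_sd = hpt_sd, cpt_mu = cpt_mu, cpt_sd = cpt_sd,
         mpt_mu = mpt_mu, mpt_sd = mpt_sd, source = source),
    class = "qst_reference"
  )
}

#' Derive reference statistics from a threshold table
#'
#' @param thresholds Data frame with columns `hpt`, `cpt`, `mpt`.
#' @param source Label for the derived statistics.
#' @return A [qst_reference()] object.
#' @export
qst_reference_from <- function(thresholds, source = "derived") {
  stopifnot(is.data.frame(thresholds))
  miss <- setdiff(.qst_modalities, names(thresholds))
  if (length(miss)) {
    stop_missing_data(paste0("missing modalities: ", paste(miss, collapse = ", ")))
  }
  qst_reference(
    hpt_mu = mean(thresholds$hpt), hpt_sd = sd(thresholds$hpt),
    cpt_mu = mean(thresholds$cpt), cpt_sd = sd(thresholds$cpt),
    mpt_mu = mean(thresholds$mpt), mpt_sd = sd(thresholds$mpt),
    source = source
  )
}

#' Normative bounds for extreme-value screening
#'
#' Holds the per-modality normative 95% percentile interval used to flag
#' extreme thresholds. The published normative values live in the QST
#' reference literature and are not bundled; they must be supplied
#' explicitly (see `inst/extdata/normative_bounds_template.json` for the
#' expected shape).
#'
#' @param hpt,cpt,mpt Length-2 numeric `c(lower, upper)` per modality.
#' @param source Free-text provenance label.
#' @return A `qst_bounds` object.
#' @export
qst_bounds <- function(hpt, cpt, mpt, source = "unspecified") {
  b <- list(hpt = as.numeric(hpt), cpt = as.numeric(cpt), mpt = as.numeric(mpt))
  for (m in names(b)) {
    if (length(b[[m]]) != 2 || any(!is.finite(b[[m]])) || b[[m]][1] >= b[[m]][2]) {
      stop_config(sprintf("bounds for `%s` must be finite c(lower, upper) with lower < upper.", m))
    }
  }
  structure(c(b, list(source = source)), class = "qst_bounds")
}

#' @export
print.qst_reference <- function(x, ...) {
  cat("QST reference statistics (", x$source, ")\n", sep = "")
  for (m in .qst_modalities) {
    cat(sprintf("  %s: mu = %.3f, sd = %.3f\n", m,
                x[[paste0(m, "_mu")]], x[[paste0(m, "_sd")]]))
  }
  invisible(x)
}

#' @export
print.qst_bounds <- function(x, ...) {
  cat("QST normative bounds (", x$source, ")\n", sep = "")
  for (m in .qst_modalities) {
    cat(sprintf("  %s: [%.3f, %.3f]\n", m, x[[m]][1], x[[m]][2]))
  }
  invisible(x)
}

# trial table -> thresholds -------------------------------------------------

#' Per-subject thresholds from a long trial table
#'
#' Aggregates raw QST trials into one threshold per subject and modality:
#' thermal modalities (`hpt`, `cpt`, `wdt`, `cdt`) with
#' [thermal_pain_threshold()] (first trial discarded), mechanical modalities
#' (`mpt`, `mdt`) with [mechanical_pain_threshold()] (log10 geometric mean),
#' and optionally T50 from a separate ratings table via [t50_from_ratings()].
#'
#' @param trials Data frame with columns `subject_id`, `modality`,
#'   `trial_index`, `value` (temperatures in degrees Celsius, forces in mN).
#' @param ratings Optional data frame with columns `subject_id`,
#'   `temperature`, `rating` for T50 estimation.
#' @return A tibble with one row per subject and one column per modality
#'   present (plus `t50` when `ratings` is given).
#' @export
qst_thresholds <- function(trials, ratings = NULL) {
  stopifnot(is.data.frame(trials))
  need <- c("subject_id", "modality", "trial_index", "value")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop_invalid(paste0("`trials` is missing columns: ", paste(miss, collapse = ", ")))
  }
  thermal <- c("hpt", "cpt", "wdt", "cdt")
  mech <- c("mpt", "mdt")
  bad <- setdiff(unique(trials$modality), c(thermal, mech))
  if (length(bad)) {
    stop_invalid(paste0("unknown modalities in `trials`: ", paste(bad, collapse = ", ")))
  }
  out <- trials |>
    dplyr::arrange(.data$subject_id, .data$modality, .data$trial_index) |>
    dplyr::group_by(.data$subject_id, .data$modality) |>
    dplyr::summarise(
      threshold = if (.data$modality[1] %in% thermal) {
        thermal_pain_threshold(.data$value)
      } else {
        mechanical_pain_threshold(.data$value)
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "modality", values_from = "threshold")
  if (!is.null(ratings)) {
    t50 <- ratings |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        t50 = t50_from_ratings(dplyr::pick("temperature", "rating")),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, t50, by = "subject_id")
  }
  out
}

# composite score -----------------------------------------------------------

#' Composite pain-sensitivity score
#'
#' Z-transforms each requested threshold against the reference statistics,
#' flips the sign of HPT and MPT (lower thresholds mean higher sensitivity),
#' and averages the adjusted z-values, so that a higher score means higher
#' pain sensitivity on a cohort-independent scale.
#'
#' @param thresholds Data frame with one row per subject carrying the
#'   requested modality columns (from [qst_thresholds()] or equivalent).
#' @param ref A [qst_reference()] object.
#' @param modalities Character subset of `c("hpt", "cpt", "mpt")`; default
#'   all three. Useful for robustness analyses on two-modality scores.
#' @return The input tibble with added columns `z_<modality>` (sign-adjusted
#'   z-values), `score` and `n_modalities_used`.
#' @export
qst_composite_score <- function(thresholds, ref,
                                modalities = c("hpt", "cpt", "mpt")) {
  stopifnot(is.data.frame(thresholds), inherits(ref, "qst_reference"))
  modalities <- match.arg(modalities, .qst_modalities, several.ok = TRUE)
  miss <- setdiff(modalities, names(thresholds))
  if (length(miss)) {
    stop_missing_data(paste0("thresholds lack requested modalities: ",
                             paste(miss, collapse = ", ")))
  }
  out <- as_tibble(thresholds)
  zs <- matrix(NA_real_, nrow(out), length(modalities),
               dimnames = list(NULL, modalities))
  for (m in modalities) {
    v <- out[[m]]
    if (any(is.na(v))) stop_missing_data(sprintf("missing `%s` values.", m))
    z <- (v - ref[[paste0(m, "_mu")]]) / ref[[paste0(m, "_sd")]]
    if (m %in% .qst_inverted) z <- -z
    zs[, m] <- z
    out[[paste0("z_", m)]] <- z
  }
  out$score <- rowMeans(zs)
  out$n_modalities_used <- length(modalities)
  out
}

#' Flag and exclude extreme QST profiles
#'
#' A modality is flagged when its threshold falls outside the normative
#' interval; subjects flagged in at least two of the three pain modalities
#' are marked for exclusion.
#'
#' @param thresholds Data frame with columns `hpt`, `cpt`, `mpt`.
#' @param bounds A [qst_bounds()] object with explicit normative intervals.
#' @return The input tibble with logical columns `flag_hpt`, `flag_cpt`,
#'   `flag_mpt`, integer `n_flags` and logical `excluded`.
#' @export
flag_extreme_qst <- function(thresholds, bounds) {
  if (!inherits(bounds, "qst_bounds")) {
    stop_config("`bounds` must be a qst_bounds object with explicit normative values.")
  }
  stopifnot(is.data.frame(thresholds))
  miss <- setdiff(.qst_modalities, names(thresholds))
  if (length(miss)) {
    stop_missing_data(paste0("thresholds lack modalities: ", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(thresholds)
  for (m in .qst_modalities) {
    out[[paste0("flag_", m)]] <-
      out[[m]] < bounds[[m]][1] | out[[m]] > bounds[[m]][2]
  }
  out$n_flags <- out$flag_hpt + out$flag_cpt + out$flag_mpt
  out$excluded <- out$n_flags >= 2
  out
}
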