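# Synthetic cohorts with a planted sparse connectivity-trait structure:
# regional timeseries whose partial-correlation network covaries with a
# latent pain-sensitivity trait, motion traces with spikes, CompCor noise
# signals, and QST trials loaded on the same trait.

#' Synthetic cohort configuration
#'
#' The generator plants a sparse effect on the precision (inverse
#' covariance) scale: for each planted edge the precision entry is shifted
#' by `effect * trait` per subject, and the diagonal is loaded to keep the
#' matrix positive-definite. QST thresholds load on the same latent trait
#' with loading `trait_loading`, with signs arranged so that a higher trait
#' means higher pain sensitivity in every modality.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of atlas-like regions; a global grey-matter-like
#'   node is appended as the last node.
#' @param n_frames Frames per subject.
#' @param tr Repetition time in seconds.
#' @param planted_edges Data frame with columns `node_i`, `node_j`,
#'   `effect`: the per-unit-trait shift of the precision entry.
#' @param trait_loading Loading of QST thresholds on the latent trait, in
#'   `[0, 1]`.
#' @param ar_coefficient Temporal AR(1) smoothing coefficient in `[0, 1)`.
#' @param motion List: `rw_sd_trans` (mm), `rw_sd_rot` (rad) random-walk
#'   step sds, `spike_prob`, `spike_amp` (mm).
#' @param qst List of reference `c(mean, sd)` per modality plus trial noise
#'   (`thermal_trial_sd` degrees Celsius, `mech_run_sd` log10 mN) and trial
#'   counts.
#' @param base_density Fraction of background (non-planted) off-diagonal
#'   precision entries.
#' @param base_strength Magnitude of background precision entries.
#' @param global_coupling Precision coupling of every region to the global
#'   node.
#' @param min_eigen Positive-definiteness floor for subject precisions.
#' @param n_noise_signals Number of CompCor noise-region signals.
#' @param seed Root seed; per-subject substreams are derived from it, so a
#'   cohort can be extended without changing existing subjects.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 60, n_regions = 20, n_frames = 200,
                         tr = 2.5,
                         planted_edges = tibble(
                           node_i = c(2L, 4L, 7L, 11L),
                           node_j = c(9L, 14L, 17L, 19L),
                           effect = c(0.35, -0.35, 0.35, -0.35)
                         ),
                         trait_loading = 0.8,
                         ar_coefficient = 0.3,
                         motion = list(rw_sd_trans = 0.008, rw_sd_rot = 1e-4,
                                       spike_prob = 0.02, spike_amp = 0.5),
                         qst = list(hpt = c(44.6, 3.0), cpt = c(12.0, 8.0),
                                    mpt = c(1.81, 0.35),
                                    thermal_trial_sd = 0.6, mech_run_sd = 0.1,
                                    n_thermal_trials = 6, n_mech_runs = 10),
                         base_density = 0.08, base_strength = 0.12,
                         global_coupling = -0.08, min_eigen = 0.05,
                         n_noise_signals = 10, seed = 1) {
  p <- n_regions + 1
  pe <- as_tibble(planted_edges)
  if (!all(c("node_i", "node_j", "effect") %in% names(pe))) {
    stop_config("`planted_edges` needs columns node_i, node_j, effect.")
  }
  if (any(pe$node_i >= pe$node_j) || any(pe$node_j > p) || any(pe$node_i < 1)) {
    stop_config("planted edges must reference node pairs with node_i < node_j <= n_regions + 1.")
  }
  if (trait_loading < 0 || trait_loading > 1) stop_config("`trait_loading` must lie in [0, 1].")
  if (ar_coefficient < 0 || ar_coefficient >= 1) stop_config("`ar_coefficient` must lie in [0, 1).")
  if (motion$spike_prob < 0 || motion$spike_prob >= 1) {
    stop_config("`spike_prob` must lie in [0, 1).")
  }
  structure(
    list(n_subjects = n_subjects, n_regions = n_regions, n_frames = n_frames,
         tr = tr, planted_edges = pe, trait_loading = trait_loading,
         ar_coefficient = ar_coefficient, motion = motion, qst = qst,
         base_density = base_density, base_strength = base_strength,
         global_coupling = global_coupling, min_eigen = min_eigen,
         n_noise_signals = n_noise_signals, seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_node_labels <- function(config) {
  c(sprintf("region_%02d", seq_len(config$n_regions)), "global")
}

synth_modules <- function(config) {
  c(paste0("module_", (seq_len(config$n_regions) - 1) %% 4 + 1), "global")
}

subject_seed <- function(config, i) {
  as.integer((as.double(config$seed) + 104729 * i) %% (.Machine$integer.max - 1)) + 1L
}

# base precision shared by all subjects (deterministic in config$seed)
base_precision <- function(config) {
  p <- config$n_regions + 1
  set.seed(config$seed)
  theta <- diag(p)
  n_bg <- round(config$base_density * p * (p - 1) / 2)
  if (n_bg > 0) {
    pairs <- feature_index_map(p)
    pick <- pairs[sample.int(nrow(pairs), n_bg), ]
    val <- sample(c(-1, 1), n_bg, replace = TRUE) * config$base_strength
    for (k in seq_len(n_bg)) {
      theta[pick$node_i[k], pick$node_j[k]] <-
        theta[pick$node_i[k], pick$node_j[k]] + val[k]
      theta[pick$node_j[k], pick$node_i[k]] <- theta[pick$node_i[k], pick$node_j[k]]
    }
  }
  theta[p, seq_len(p - 1)] <- theta[p, seq_len(p - 1)] + config$global_coupling
  theta[seq_len(p - 1), p] <- theta[p, seq_len(p - 1)]
  theta
}

#' Subject-level precision matrix
#'
#' Reconstructs the generating precision matrix for a given trait value:
#' base precision plus `effect * trait` on every planted edge, diagonally
#' loaded so the smallest eigenvalue is at least `min_eigen`.
#'
#' @param config A [synth_config()].
#' @param trait Latent trait value for the subject.
#' @param base Precomputed base precision (internal use; recomputed from
#'   the config when omitted).
#' @return A positive-definite precision matrix.
#' @export
subject_precision <- function(config, trait, base = NULL) {
  theta <- if (is.null(base)) base_precision(config) else base
  pe <- config$planted_edges
  for (k in seq_len(nrow(pe))) {
    i <- pe$node_i[k]; j <- pe$node_j[k]
    theta[i, j] <- theta[i, j] + pe$effect[k] * trait
    theta[j, i] <- theta[i, j]
  }
  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < config$min_eigen) {
    theta <- theta + diag(config$min_eigen - ev_min, nrow(theta))
  }
  if (min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop_config("base precision is not positive-definite after loading.")
  }
  theta
}

#' Synthetic motion trace
#'
#' Random-walk rigid-body parameters plus Bernoulli displacement spikes
#' whose amplitude exceeds the usual FD threshold by construction.
#'
#' @param config A [synth_config()].
#' @param seed Seed for this trace (defaults to the config seed).
#' @return List with `motion` (frames x 6 matrix, rotations in radians then
#'   translations in mm) and `spike_frames` (frames at which a spike was
#'   injected).
#' @export
generate_motion <- function(config, seed = config$seed) {
  set.seed(seed)
  tt <- config$n_frames
  mo <- config$motion
  m <- cbind(
    matrix(apply(matrix(rnorm(tt * 3, sd = mo$rw_sd_rot), tt), 2, cumsum), tt),
    matrix(apply(matrix(rnorm(tt * 3, sd = mo$rw_sd_trans), tt), 2, cumsum), tt)
  )
  colnames(m) <- .motion_cols
  spikes <- which(runif(tt) < mo$spike_prob)
  spikes <- spikes[spikes > 1]
  m[spikes, 4] <- m[spikes, 4] + mo$spike_amp
  list(motion = m, spike_frames = spikes)
}

#' Generate a synthetic cohort
#'
#' Per subject: a latent trait `s ~ N(0, 1)`; frames drawn from the
#' zero-mean Gaussian with covariance `solve(subject_precision(config, s))`
#' and AR(1)-smoothed; a motion trace with spikes; CompCor-style noise
#' signals; and QST trials whose underlying thresholds load on the trait.
#' Bit-for-bit reproducible from `(config, config$seed)`; subjects use
#' independent substreams of the root seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_cohort` object; see [ground_truth()],
#'   [cohort_features()], [cohort_scores()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  labels <- synth_node_labels(config)
  modules <- synth_modules(config)
  base <- base_precision(config)  # also validates PD path below
  p <- config$n_regions + 1
  phi <- config$ar_coefficient
  qc <- config$qst

  subjects <- purrr::map(seq_len(config$n_subjects), function(i) {
    set.seed(subject_seed(config, i))
    s <- rnorm(1)
    # base precision precomputed above: subject_precision() would reseed
    # the RNG and collapse the per-subject substreams
    theta <- subject_precision(config, s, base = base)
    sigma <- solve(theta)
    r <- chol(sigma)
    innov <- matrix(rnorm(config$n_frames * p), config$n_frames, p) %*% r
    if (phi > 0) {
      x <- apply(innov * sqrt(1 - phi^2), 2, function(v) {
        as.numeric(stats::filter(v, phi, method = "recursive"))
      })
      x[1, ] <- innov[1, ]
    } else {
      x <- innov
    }
    ts <- regional_timeseries(x, labels = labels, tr = config$tr,
                              modules = modules)
    mot <- generate_motion(config, seed = subject_seed(config, i) + 1L)
    noise <- {
      drift <- matrix(rnorm(config$n_frames * 3), config$n_frames, 3)
      drift <- apply(drift, 2, cumsum)
      mix <- matrix(rnorm(3 * config$n_noise_signals), 3)
      drift %*% mix + matrix(rnorm(config$n_frames * config$n_noise_signals),
                             config$n_frames)
    }
    # modality latents: z_m = lambda * s + sqrt(1 - lambda^2) * eps_m,
    # higher z_m = more sensitive in every modality
    lam <- config$trait_loading
    zm <- lam * s + sqrt(1 - lam^2) * rnorm(3)
    hpt <- qc$hpt[1] - qc$hpt[2] * zm[1]
    cpt <- qc$cpt[1] + qc$cpt[2] * zm[2]
    mpt <- qc$mpt[1] - qc$mpt[2] * zm[3]
    id <- sprintf("sub%03d", i)
    trials <- dplyr::bind_rows(
      tibble(subject_id = id, modality = "hpt",
             trial_index = seq_len(qc$n_thermal_trials),
             value = hpt + rnorm(qc$n_thermal_trials, sd = qc$thermal_trial_sd)),
      tibble(subject_id = id, modality = "cpt",
             trial_index = seq_len(qc$n_thermal_trials),
             value = cpt + rnorm(qc$n_thermal_trials, sd = qc$thermal_trial_sd)),
      tibble(subject_id = id, modality = "mpt",
             trial_index = seq_len(qc$n_mech_runs),
             value = 10^(mpt + rnorm(qc$n_mech_runs, sd = qc$mech_run_sd)))
    )
    list(subject_id = id, trait = s, theta = theta, ts = ts,
         motion = mot$motion, spike_frames = mot$spike_frames,
         noise_signals = noise, trials = trials)
  })

  structure(
    list(config = config, subjects = subjects,
         reference = qst_reference(
           hpt_mu = qc$hpt[1], hpt_sd = qc$hpt[2],
           cpt_mu = qc$cpt[1], cpt_sd = qc$cpt[2],
           mpt_mu = qc$mpt[1], mpt_sd = qc$mpt[2],
           source = "synthetic population"
         )),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d+1 nodes, %d frames (TR %g s), %d planted edges\n",
    cfg$n_subjects, cfg$n_regions, cfg$n_frames, cfg$tr,
    nrow(cfg$planted_edges)))
  invisible(x)
}

#' Generating ground truth of a synthetic cohort
#'
#' @param cohort A `synth_cohort`.
#' @return List with `planted_edges` (including node labels), `traits`
#'   (tibble of subject latent traits) and `reference` (the generating QST
#'   statistics).
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  labels <- synth_node_labels(cohort$config)
  pe <- cohort$config$planted_edges |>
    dplyr::mutate(label_i = labels[.data$node_i], label_j = labels[.data$node_j])
  tr <- purrr::map(cohort$subjects,
                   ~tibble(subject_id = .x$subject_id, trait = .x$trait)) |>
    purrr::list_rbind()
  list(planted_edges = pe, traits = tr, reference = cohort$reference)
}

#' Connectome feature matrix of a cohort
#'
#' Estimates the partial-correlation matrix per subject and stacks the
#' upper-triangle vectors into a subjects x features matrix whose columns
#' are named `"<label_i>--<label_j>"`.
#'
#' @param cohort A `synth_cohort` (or a list of `regional_ts`).
#' @param estimator Passed to [partial_correlation()].
#' @return Matrix with attribute `feature_map` (the index/pair tibble).
#' @export
cohort_features <- function(cohort, estimator = "shrinkage") {
  ts_list <- if (inherits(cohort, "synth_cohort")) {
    purrr::map(cohort$subjects, "ts")
  } else {
    cohort
  }
  feats <- purrr::map(ts_list, function(ts) {
    vectorize_upper(partial_correlation(ts, estimator = estimator))
  })
  map <- dplyr::select(feats[[1]], "feature_index", "label_i", "label_j")
  x <- do.call(rbind, purrr::map(feats, "value"))
  colnames(x) <- paste0(map$label_i, "--", map$label_j)
  if (inherits(cohort, "synth_cohort")) {
    rownames(x) <- purrr::map_chr(cohort$subjects, "subject_id")
  }
  structure(x, feature_map = map)
}

#' Composite pain-sensitivity scores of a cohort
#'
#' Runs the QST scoring pipeline on the cohort's generated trials against
#' a reference (by default the cohort's own generating statistics).
#'
#' @param cohort A `synth_cohort`.
#' @param ref A [qst_reference()]; defaults to the generating statistics.
#' @return Tibble with thresholds, z-values and `score` per subject.
#' @export
cohort_scores <- function(cohort, ref = cohort$reference) {
  stopifnot(inherits(cohort, "synth_cohort"))
  trials <- purrr::map(cohort$subjects, "trials") |> purrr::list_rbind()
  qst_thresholds(trials) |>
    qst_composite_score(ref)
}
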