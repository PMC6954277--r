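test_that("thermal threshold discards the first trial and averages the rest", {
  expect_equal(thermal_pain_threshold(c(44.0, 44.6, 44.2, 44.8, 44.4, 44.5)), 44.5)
  expect_equal(thermal_pain_threshold(rep(45, 6)), 45)
  # works for any trial count >= 2, not just the protocol's 6
  expect_equal(thermal_pain_threshold(c(40, 41, 43)), 42)
  expect_error(thermal_pain_threshold(44), class = "rpnsig_error_invalid_input")
  expect_error(thermal_pain_threshold(c(44, NA)), class = "rpnsig_error_invalid_input")
})

test_that("thermal threshold is permutation-invariant in trials 2..n", {
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(6, 45, 1)
    shuffled <- c(x[1], sample(x[-1]))
    expect_equal(thermal_pain_threshold(shuffled), thermal_pain_threshold(x))
  }
})

test_that("mechanical threshold is the log10 geometric mean of run forces", {
  expect_equal(mechanical_pain_threshold(rep(64, 10)), log10(64))
  expect_equal(mechanical_pain_threshold(c(8, 16, 32, 64, 128, 8, 16, 32, 64, 128)),
               1.5051499783, tolerance = 1e-9)
  expect_error(mechanical_pain_threshold(c(32, 0)), class = "rpnsig_error_invalid_input")
  expect_error(mechanical_pain_threshold(c(32, -4)), class = "rpnsig_error_invalid_input")
})

test_that("T50 recovers the rating-50 crossing of the generating curve", {
  # quadratic generating curve: closed-form ascending root at 42.5 + sqrt(15.125)
  tt <- seq(42.5, 48, length.out = 15)
  quad <- data.frame(temperature = tt, rating = (100 / 30.25) * (tt - 42.5)^2)
  expect_equal(t50_from_ratings(quad), 42.5 + sqrt(50 * 30.25 / 100), tolerance = 1e-6)

  # exactly linear ratings: fitted quadratic term ~ 0, linear root at 46
  tl <- seq(42.5, 48, length.out = 10)
  lin <- data.frame(temperature = tl, rating = 12.5 * (tl - 42))
  expect_equal(t50_from_ratings(lin), 46.0, tolerance = 1e-6)

  # rating 50 never reached within the stimulated range
  low <- data.frame(temperature = tt, rating = 10 + 2 * (tt - 42.5))
  expect_error(t50_from_ratings(low), class = "rpnsig_error_no_solution")
  # ratings that do not vary at all: degenerate fit
  flat <- data.frame(temperature = tt, rating = rep(10, length(tt)))
  expect_error(t50_from_ratings(flat), class = "rpnsig_error_degenerate_fit")
})

test_that("composite score applies z-transform, sign flips and averaging", {
  ref <- qst_reference(hpt_mu = 44.6, hpt_sd = 3, cpt_mu = 12, cpt_sd = 8,
                       mpt_mu = 1.81, mpt_sd = 0.35, source = "test")
  at_mean <- tibble::tibble(subject_id = "a", hpt = 44.6, cpt = 12, mpt = 1.81)
  expect_equal(qst_composite_score(at_mean, ref)$score, 0)

  # one sd towards sensitivity in every modality -> score +1
  sens <- tibble::tibble(subject_id = "a", hpt = 44.6 - 3, cpt = 12 + 8,
                         mpt = 1.81 - 0.35)
  expect_equal(qst_composite_score(sens, ref)$score, 1)

  # hpt two sd above the mean only: (-2 + 0 + 0) / 3
  hi_hpt <- tibble::tibble(subject_id = "a", hpt = 44.6 + 6, cpt = 12, mpt = 1.81)
  expect_equal(qst_composite_score(hi_hpt, ref)$score, -2 / 3)

  # configurable modality subsets record what was used
  two <- qst_composite_score(sens, ref, modalities = c("hpt", "cpt"))
  expect_equal(two$n_modalities_used, 2)
  expect_equal(two$score, 1)

  expect_error(qst_composite_score(dplyr::select(sens, -"mpt"), ref),
               class = "rpnsig_error_missing_data")
})

test_that("composite score is invariant to affine re-units when the reference is re-derived", {
  set.seed(11)
  pop <- tibble::tibble(subject_id = as.character(1:40),
                        hpt = rnorm(40, 44.6, 3), cpt = rnorm(40, 12, 8),
                        mpt = rnorm(40, 1.81, 0.35))
  s1 <- qst_composite_score(pop, qst_reference_from(pop))
  # re-unit: HPT to Fahrenheit-like scale, MPT shifted
  pop2 <- dplyr::mutate(pop, hpt = 1.8 * hpt + 32, mpt = mpt + 3)
  s2 <- qst_composite_score(pop2, qst_reference_from(pop2))
  expect_equal(s2$score, s1$score, tolerance = 1e-12)
})

test_that("population scored against itself has mean 0 and the covariance-predicted variance", {
  set.seed(12)
  n <- 200
  # correlated modalities via a shared latent factor
  lat <- rnorm(n)
  pop <- tibble::tibble(
    subject_id = as.character(seq_len(n)),
    hpt = 44.6 - 3 * (0.7 * lat + rnorm(n, sd = sqrt(1 - 0.49))),
    cpt = 12 + 8 * (0.7 * lat + rnorm(n, sd = sqrt(1 - 0.49))),
    mpt = 1.81 - 0.35 * (0.7 * lat + rnorm(n, sd = sqrt(1 - 0.49)))
  )
  sc <- qst_composite_score(pop, qst_reference_from(pop))
  expect_lt(abs(mean(sc$score)), 1e-12)
  # oracle: var of the mean of the three adjusted z-columns from their
  # covariance matrix directly
  zc <- cbind(sc$z_hpt, sc$z_cpt, sc$z_mpt)
  expect_equal(var(sc$score), mean(cov(zc)), tolerance = 1e-12)
  # and the score equals the row mean of the adjusted z-values exactly
  expect_equal(sc$score, rowMeans(zc))
})

test_that("extreme-value screening excludes on >= 2 flagged modalities", {
  bounds <- qst_bounds(hpt = c(40, 48), cpt = c(0, 25), mpt = c(1, 2.5),
                       source = "test")
  th <- tibble::tibble(
    subject_id = c("ok", "one", "two", "three"),
    hpt = c(44, 39, 39, 55),
    cpt = c(10, 10, 30, 40),
    mpt = c(1.8, 1.8, 1.8, 0.2)
  )
  fl <- flag_extreme_qst(th, bounds)
  expect_equal(fl$n_flags, c(0L, 1L, 2L, 3L))
  expect_equal(fl$excluded, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(flag_extreme_qst(th, list(hpt = c(40, 48))),
               class = "rpnsig_error_config")
})

test_that("the shipped bounds template refuses to screen until filled in", {
  tmpl <- system.file("extdata", "normative_bounds_template.json", package = "rpnsig")
  expect_error(read_qst_bounds_json(tmpl), class = "rpnsig_error_config")
})

test_that("long trial tables aggregate to per-subject thresholds", {
  trials <- dplyr::bind_rows(
    tibble::tibble(subject_id = "s1", modality = "hpt", trial_index = 1:6,
                   value = c(44.0, 44.6, 44.2, 44.8, 44.4, 44.5)),
    tibble::tibble(subject_id = "s1", modality = "cpt", trial_index = 1:6,
                   value = c(14, 10, 11, 9, 10, 10)),
    tibble::tibble(subject_id = "s1", modality = "mpt", trial_index = 1:10,
                   value = c(8, 16, 32, 64, 128, 8, 16, 32, 64, 128))
  )
  th <- qst_thresholds(trials)
  expect_equal(th$hpt, 44.5)
  expect_equal(th$cpt, 10)
  expect_equal(th$mpt, 1.5051499783, tolerance = 1e-9)
  # unknown modality is rejected, not silently mis-scored
  bad <- dplyr::mutate(trials, modality = ifelse(modality == "mpt", "xx", modality))
  expect_error(qst_thresholds(bad), class = "rpnsig_error_invalid_input")
})
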