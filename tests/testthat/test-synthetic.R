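# Synthetic cohort generator: determinism, coupling-to-correlation
# behaviour, bookkeeping and hemisphere confinement.

test_that("identical spec and seed reproduce bit-identical samples", {
  spec <- toy_spec()
  sch <- coupling_schedule()
  a <- generate_segment(spec, sch, "bilateral", seed = 7)
  b <- generate_segment(spec, sch, "bilateral", seed = 7)
  expect_identical(a$segment$samples, b$segment$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_segment(spec, sch, "bilateral", seed = 8)
  expect_false(identical(a$segment$samples, c2$segment$samples))
})

test_that("zero coupling gains leave channels uncorrelated at the null level", {
  spec <- toy_spec()
  sch <- coupling_schedule(within_base = 0, between_base = 0,
                           post_sync_boost = 0, post_between_boost = 0)
  g <- generate_segment(spec, sch, "interictal", seed = 3)
  raw <- sliding_correlation(g$segment, win = 1, step = 1)
  W <- dim(raw$matrices)[3]
  expect_gte(W, 100)
  offdiag <- apply(raw$matrices, 3, function(A) mean(abs(A[upper.tri(A)])))
  # |r| of independent series over n=500 samples has mean ~ sqrt(2/(pi n));
  # allow 3 standard errors of the window-averaged estimate
  n <- 500
  exp_abs <- sqrt(2 / (pi * n))
  se <- sqrt((1 / n) * (1 - 2 / pi)) / sqrt(W * 28)
  expect_lt(abs(mean(offdiag) - exp_abs), 3 * se + 0.002)
})

test_that("shared-community channels approach perfect correlation as noise vanishes", {
  spec <- toy_spec()
  for (sigma in c(0.5, 0.05)) {
    sch <- coupling_schedule(n_communities = 2, noise_sigma = sigma)
    g <- generate_segment(spec, sch, "interictal", seed = 5)
    same_com <- which(g$ground_truth$communities == g$ground_truth$communities[1])
    raw <- sliding_correlation(g$segment, win = 1, step = 1)
    r <- mean(raw$matrices[same_com[1], same_com[2], ])
    if (sigma == 0.5) expect_gt(r, 0.6) else expect_gt(r, 0.99)
  }
})

test_that("cohort bookkeeping honours requested multiplicities and sub-seeds", {
  spec <- toy_spec()
  spec$n_focal <- 2L; spec$n_bilateral <- 1L; spec$n_interictal <- 3L
  cohort <- generate_cohort(spec, coupling_schedule())
  expect_length(cohort, 6)
  conds <- vapply(cohort, function(x) x$ground_truth$condition, "")
  expect_equal(as.vector(table(factor(conds, c("focal", "bilateral",
                                               "interictal")))),
               c(2, 1, 3))
  seeds <- vapply(cohort, function(x) x$ground_truth$seed, 0)
  expect_equal(anyDuplicated(seeds), 0)
  # single-interictal cohort: gain schedule is time-constant
  spec$n_focal <- 0L; spec$n_bilateral <- 0L; spec$n_interictal <- 1L
  one <- generate_cohort(spec, coupling_schedule())
  expect_length(one, 1)
  for (kn in one[[1]]$ground_truth$within_gain_knots)
    expect_equal(length(unique(kn$gain)), 1)
})

test_that("study-scale cohort counts add up to 134 segments", {
  spec <- cohort_spec()                   # defaults: 49 / 18 / 67
  conds <- rep(c("focal", "bilateral", "interictal"),
               c(spec$n_focal, spec$n_bilateral, spec$n_interictal))
  expect_length(conds, 134)
  # generate two real segments at full scale to confirm shape + annotations
  sch <- coupling_schedule()
  g <- generate_segment(cohort_spec(n_channels = 6), sch, "focal", seed = 2)
  expect_equal(dim(g$segment$samples), c(6, 1500 * 500))
  expect_equal(g$segment$onset_time, 900)
  expect_true("seizure_onset" %in% g$segment$annotations$label)
})

test_that("focal spread never touches contralateral communities", {
  spec <- toy_spec()
  sch <- coupling_schedule(preictal_magnitude = 0.4)
  gt_f <- generate_segment(spec, sch, "focal", seed = 1)$ground_truth
  hemi_of_com <- vapply(seq_along(gt_f$amplitude_knots), function(k)
    gt_f$hemisphere[which(gt_f$communities == k)[1]], "")
  onset_hemi <- hemi_of_com[gt_f$onset_community]
  for (k in seq_along(gt_f$amplitude_knots)) {
    kn <- gt_f$amplitude_knots[[k]]
    changes <- length(unique(kn$gain)) > 1
    if (hemi_of_com[k] != onset_hemi) expect_false(changes)
    # the focal pre-onset mixing gains stay at baseline (no signature)
    expect_equal(unique(gt_f$within_gain_knots[[k]]$gain), sch$within_base)
  }
  # bilateral spread recruits every community; contralateral ones only
  # after the spread delay
  gt_b <- generate_segment(spec, sch, "bilateral", seed = 1)$ground_truth
  for (k in seq_along(gt_b$amplitude_knots)) {
    kn <- gt_b$amplitude_knots[[k]]
    expect_gt(max(kn$gain), 1)
    t_rise <- min(kn$t[kn$gain > 1])
    if (hemi_of_com[k] != onset_hemi)
      expect_gte(t_rise, spec$onset_offset + sch$spread_delay)
    else expect_lte(t_rise, spec$onset_offset + sch$ramp)
  }
  # the bilateral pre-onset signature lives in the mixing gains
  expect_gt(gt_b$within_gain_knots[[1]]$gain[1], sch$within_base)
  expect_lt(gt_b$between_gain_knots$gain[1], sch$between_base)
  # interictal ground truth records constant gains and the pseudo-onset
  gt_i <- generate_segment(spec, sch, "interictal", seed = 1)$ground_truth
  expect_equal(gt_i$onset_time, spec$onset_offset)
  for (kn in gt_i$amplitude_knots) expect_equal(unique(kn$gain), 1)
})

test_that("invalid generator inputs are rejected", {
  spec <- toy_spec()
  expect_error(generate_segment(spec, coupling_schedule(), "ictal"))
  expect_error(cohort_spec(n_channels = 2), "at least 4")
  expect_error(cohort_spec(hemisphere_split = 1), "hemisphere_split")
  expect_error(cohort_spec(fs = -1), "fs")
  expect_error(cohort_spec(onset_offset = 2000, segment_length = 1500),
               "onset_offset")
  expect_error(coupling_schedule(within_base = -1))
})

test_that("preictal signature raises pre-onset modularity and lowers spectral radius", {
  # single-segment check of the injected direction (the cohort-level
  # recovery test lives in the acceptance suite)
  spec <- toy_spec()
  cfg <- run_config(spec, coupling_schedule(), boot_B = 10, perm_B = 10)
  base <- generate_segment(spec, coupling_schedule(), "bilateral", seed = 21)
  inj <- generate_segment(spec, coupling_schedule(preictal_magnitude = 0.5),
                          "bilateral", seed = 21)
  mt_base <- process_segment(base$segment, cfg)
  mt_inj <- process_segment(inj$segment, cfg)
  pre <- mt_base$time_min < 0
  expect_gt(mean(mt_inj$modularity[pre]), mean(mt_base$modularity[pre]))
  expect_lt(mean(mt_inj$spectral_radius[pre]), mean(mt_base$spectral_radius[pre]))
})
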