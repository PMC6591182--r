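test_that("phantom geometry has the promised structure and symmetry", {
  cfg <- phantom_config(n_targets_bilateral = 1L, n_targets_midline = 1L,
                        grid_shape = c(41L, 41L, 41L))
  ph <- make_phantom_labels(cfg)
  tab <- ph$table
  expect_equal(sum(tab$role == "seed"), 1)
  expect_equal(sum(tab$role == "target"), 3)
  expect_equal(sum(tab$role == "exclusion"), 1)
  expect_equal(tab$hemisphere[tab$role == "seed"], "midline")

  # bilateral members are mirror images: identical voxel counts
  counts <- table(ph$labels$labels[ph$labels$labels > 0])
  pairs <- bilateral_pairs(tab)
  expect_equal(unname(counts[as.character(pairs$left)]),
               unname(counts[as.character(pairs$right)]))

  # labelling is a partition: voxel sets of distinct labels are disjoint
  # (recompute each ROI sphere independently and scan for shared voxels)
  cent <- attr(ph$labels, "roi_centres_vox")
  vox_sets <- lapply(cent, function(cc) {
    g <- expand.grid(x = 0:40, y = 0:40, z = 0:40)
    d2 <- (g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2
    which(d2 <= cfg$roi_radius^2)
  })
  for (i in seq_along(vox_sets))
    for (j in seq_len(i - 1))
      expect_length(intersect(vox_sets[[i]], vox_sets[[j]]), 0)

  # a grid too small to host the ROIs is refused
  expect_error(make_phantom_labels(
    phantom_config(grid_shape = c(9L, 9L, 9L), roi_radius = 4)),
    "grid")
})

test_that("subject weights follow the stated log-normal model", {
  cfg <- phantom_config(subject_sigma = 0, lateralization_shift = 1.25,
                        n_targets_bilateral = 2L, n_targets_midline = 1L)
  set.seed(1)
  w <- sample_subject_weights(cfg)
  left <- c(1, 3); right <- c(2, 4)
  expect_equal(w[right], cfg$true_weights[right])     # sigma 0: no noise
  expect_equal(w[left], cfg$true_weights[left] * 1.25)
  expect_equal(w[5], cfg$true_weights[5])             # midline unshifted

  cfg2 <- phantom_config(subject_sigma = 0.4, n_targets_bilateral = 1L,
                         n_targets_midline = 1L)
  set.seed(2)
  draws <- t(replicate(10000, sample_subject_weights(cfg2)))
  lr <- sweep(log(draws), 2, log(cfg2$true_weights))
  # Monte-Carlo check of the Normal(0, sigma^2) log-perturbation
  z <- abs(colMeans(lr)) / (apply(lr, 2, sd) / sqrt(nrow(lr)))
  expect_true(all(z < 3))
  expect_equal(apply(lr, 2, sd), rep(0.4, 3), tolerance = 0.02)
})

test_that("intended streamline counts always conserve the total", {
  for (s in 1:5) {
    cfg <- phantom_config(n_streamlines = 157L + s, seed = s,
                          noise_exclusion_frac = 0.07,
                          noise_multitarget_frac = 0.03,
                          noise_offtarget_frac = 0.11)
    ph <- make_phantom_labels(cfg)
    set.seed(s)
    w <- sample_subject_weights(cfg)
    sub <- generate_subject_tractogram(ph$labels, ph$table, w, cfg)
    expect_equal(sum(sub$ground_truth$intended_counts), cfg$n_streamlines)
    expect_equal(length(sub$ground_truth$intended), cfg$n_streamlines)
  }
})

test_that("cohorts are bit-identical under the same configuration", {
  cfg <- tiny_phantom_config(n_streamlines = 120L)
  c1 <- generate_cohort(cfg, 3)
  c2 <- generate_cohort(cfg, 3)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(phantom_config(n_streamlines = 120L,
                                       n_targets_bilateral = 2L,
                                       n_targets_midline = 1L,
                                       seed = 43L), 3)
  expect_false(identical(serialize(c1, NULL), serialize(c3, NULL)))
  expect_length(generate_cohort(cfg, 1)$subjects, 1)
})

test_that("assignment recovers intended outcomes on phantom tractograms", {
  cfg <- phantom_config(n_streamlines = 500L, seed = 9L)
  coh <- generate_cohort(cfg, 2)
  for (sub in coh$subjects) {
    asg <- assign_streamlines(sub$tractogram, coh$labels, coh$table)
    agree <- mean(asg$outcome == sub$ground_truth$intended)
    expect_gte(agree, 0.99)
  }
})

test_that("noise-free phantoms recover the volume-corrected true weights", {
  cfg <- phantom_config(n_streamlines = 2000L, subject_sigma = 0,
                        lateralization_shift = 1, noise_exclusion_frac = 0,
                        noise_multitarget_frac = 0, noise_offtarget_frac = 0,
                        seed = 31L)
  coh <- generate_cohort(cfg, 6)
  profs <- lapply(coh$subjects, function(s)
    subject_profile(assign_streamlines(s$tractogram, coh$labels, coh$table),
                    coh$labels, coh$table))
  summ <- summarize_group(profs)
  want <- expected_delta_norm(cfg, coh)
  se <- summ$sd / sqrt(length(profs))
  se <- pmax(se, 1e-3)   # guard exact-zero spread
  expect_true(all(abs(summ$mean_delta_norm - want) <= 3 * se))
})

test_that("between-subject spread of delta_norm grows with subject_sigma", {
  med_cov <- vapply(c(0.1, 0.3, 0.6), function(sg) {
    cfg <- phantom_config(subject_sigma = sg, n_streamlines = 800L, seed = 77L)
    sim <- simulate_cohort_profiles(cfg, 15)
    mu <- colMeans(sim$profiles)
    cv <- apply(sim$profiles, 2, sd) / mu
    median(cv[mu > 0])
  }, numeric(1))
  expect_true(all(med_cov > 0))
  expect_true(all(diff(med_cov) > 0))
})
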