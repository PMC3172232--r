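test_that("default design reproduces the study timing", {
  d <- study_design()
  expect_equal(d$volumes_per_run, 245L)
  expect_equal(d$stimuli_per_condition, 14L)
  expect_equal(d$onsets_s, c(40, 110, 180, 250, 320, 390, 460))
  ev <- design_events(d, "painful")
  expect_true(all(ev$onset >= 20))
  expect_true(all(ev$onset + ev$duration <= d$run_seconds))
})

test_that("non-integer volume counts are a configuration error", {
  expect_error(study_design(tr_seconds = 4), "whole number")
  # 490 / 3.5 = 140 volumes: valid
  expect_equal(study_design(tr_seconds = 3.5)$volumes_per_run, 140L)
})

test_that("an 8 mm sphere on a 4 mm grid centered on a voxel covers 33 voxels", {
  # independent oracle: brute-force enumeration of integer voxel offsets
  offs <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  n_expected <- sum(16 * (offs$i^2 + offs$j^2 + offs$k^2) <= 64)
  expect_equal(n_expected, 33L)
  atlas <- small_atlas()
  expect_equal(atlas$regions$n_voxels, rep(33L, 3))
})

test_that("effect maps are zero without regions and equal amplitudes inside", {
  atlas <- null_atlas()
  expect_true(all(atlas$effect_pain == 0))
  expect_true(all(atlas$effect_nonpain == 0))
  a2 <- small_atlas()
  v <- a2$region_voxels[[1]]
  expect_true(all(a2$effect_pain[v] == 0.5))
  expect_true(all(a2$effect_nonpain[v] == 0.1))
  outside <- setdiff(seq_len(prod(a2$dim)), unlist(a2$region_voxels))
  expect_true(all(a2$effect_pain[outside] == 0))
})

test_that("a region sphere outside the grid is an error", {
  regions <- dplyr::mutate(default_regions()[1, ], x_mm = 500)
  expect_error(
    make_atlas(grid_shape = c(12, 12, 12), regions = regions, n_artifacts = 0),
    "covers no voxel"
  )
})

test_that("simulation is bit-identical under the same seed", {
  atlas <- tiny_atlas()
  d <- study_design()
  s1 <- simulate_subject(d, atlas, seed = 5)
  s2 <- simulate_subject(d, atlas, seed = 5)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  expect_identical(s1$runs[[4]]$data, s2$runs[[4]]$data)
  s3 <- simulate_subject(d, atlas, seed = 6)
  expect_false(identical(s1$runs[[1]]$data, s3$runs[[1]]$data))
})

test_that("noiseless simulation round-trips planted amplitudes exactly", {
  atlas <- small_atlas()
  subj <- noiseless_subject(atlas)
  ex <- extract_examples(subj)
  expect_equal(nrow(ex), 28L)
  pain_vox <- atlas$region_voxels[[1]]
  n_v <- length(pain_vox)
  for (i in which(ex$label == 1)[1:3]) {
    expect_equal(ex$psc[[i]][pain_vox], rep(0.5, n_v), tolerance = 1e-10)
  }
  for (i in which(ex$label == -1)[1:3]) {
    expect_equal(ex$psc[[i]][pain_vox], rep(0.1, n_v), tolerance = 1e-10)
  }
  # gain scales the planted amplitude linearly
  ex2 <- extract_examples(noiseless_subject(atlas, gain = 2))
  i <- which(ex2$label == 1)[1]
  expect_equal(ex2$psc[[i]][pain_vox], rep(1.0, n_v), tolerance = 1e-10)
})

test_that("planted artifact voxels exceed the 3% filter in every example", {
  atlas <- small_atlas(n_artifacts = 3, seed = 9)
  subj <- noiseless_subject(atlas)
  ex <- extract_examples(subj)
  for (i in seq_len(nrow(ex))) {
    expect_true(all(abs(ex$psc[[i]][atlas$artifact_voxels]) > 3))
  }
})

test_that("default-parameter PSC scale is realistic outside artifacts", {
  atlas <- small_atlas(n_artifacts = 3, seed = 10)
  subj <- simulate_subject(study_design(), atlas, seed = 20)
  ex <- extract_examples(subj)
  gray_non_art <- setdiff(which(atlas$gray), atlas$artifact_voxels)
  vals <- abs(unlist(lapply(ex$psc, function(p) p[gray_non_art])))
  expect_lt(stats::quantile(vals, 0.95), 3)
})

test_that("cohorts draw distinct per-subject gains reproducibly", {
  atlas <- tiny_atlas()
  d <- study_design()
  c1 <- simulate_cohort(2, d, atlas, seed = 3)
  c2 <- simulate_cohort(2, d, atlas, seed = 3)
  expect_identical(c1[[1]]$runs[[1]]$data, c2[[1]]$runs[[1]]$data)
  expect_false(c1[[1]]$gain == c1[[2]]$gain)
  c3 <- simulate_cohort(2, d, atlas, seed = 4)
  expect_false(identical(c1[[1]]$runs[[1]]$data, c3[[1]]$runs[[1]]$data))
  # same planted amplitudes regardless of seed
  expect_identical(atlas$effect_pain, atlas$effect_pain)
})

test_that("streaming extraction matches batch simulate-then-extract", {
  atlas <- tiny_atlas()
  d <- study_design()
  batch <- purrr::map_dfr(
    simulate_cohort(2, d, atlas, seed = 8), extract_examples
  )
  streamed <- simulate_cohort_examples(2, d, atlas, seed = 8)
  expect_equal(streamed$psc, batch$psc)
  expect_equal(streamed$label, batch$label)
})

test_that("dataset export round-trips events and metadata", {
  atlas <- tiny_atlas()
  d <- study_design()
  cohort <- simulate_cohort(1, d, atlas, seed = 2)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(cohort, dir, atlas)
  expect_equal(manifest$n_subjects, 1L)
  expect_length(list.files(file.path(dir, "sub-01"), pattern = "bold"), 4L)
  expect_length(list.files(file.path(dir, "sub-01"), pattern = "events"), 4L)
  expect_true(file.exists(file.path(dir, "gray_mask.nii.gz")))

  back <- read_dataset(dir)
  expect_equal(length(back$subjects), 1L)
  run1 <- back$subjects[[1]]$runs[[1]]
  orig1 <- cohort[[1]]$runs[[1]]
  expect_identical(run1$events$onset, orig1$events$onset)
  expect_identical(run1$events$trial_type, orig1$events$trial_type)
  expect_equal(run1$condition, orig1$condition)
  expect_equal(back$gray, atlas$gray)
  expect_equal(back$affine, atlas$affine, ignore_attr = TRUE)
  expect_equal(run1$data, orig1$data, tolerance = 1e-6)
})
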