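make_run <- function(data, tr = 2, affine = diag(c(4, 4, 4, 1)),
                     events = tibble::tibble(onset = 40, duration = 30,
                                             trial_type = "painful")) {
  structure(
    list(data = data, affine = affine, tr_seconds = tr, events = events,
         condition = "painful", run_id = "run-01", subject_id = "sub-01"),
    class = "bold_run"
  )
}

test_that("smoothing with fwhm 0 is the identity and constants pass through", {
  arr <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  expect_identical(smooth_volume(arr, 0, voxel_mm = 4), arr)
  const <- array(7, c(8, 8, 8))
  expect_equal(smooth_volume(const, 4, voxel_mm = 4), const, tolerance = 1e-12)
})

test_that("a delta function spreads to the 3D Gaussian kernel and keeps its sum", {
  arr <- array(0, c(9, 9, 9))
  arr[5, 5, 5] <- 1
  sm <- smooth_volume(arr, 4, voxel_mm = 4)
  # direct kernel construction oracle
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 4   # in voxels
  r <- max(1, ceiling(4 * sigma))
  w1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  central <- w1[r + 1]^3
  expect_equal(sm[5, 5, 5], central, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("anisotropic voxels trigger a warning but still smooth", {
  arr <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  expect_warning(smooth_volume(arr, 4, voxel_mm = c(2, 4, 4)), "Anisotropic")
})

test_that("window-to-frame mapping gives 10 baseline and 12 stimulus frames at TR 2", {
  expect_length(painmvpa:::frames_in_window(245, 2, 20, 40), 10L)
  expect_length(painmvpa:::frames_in_window(245, 2, 46, 70), 12L)
  # frame counts follow the seconds when TR changes
  expect_length(painmvpa:::frames_in_window(490, 1, 20, 40), 20L)
  expect_length(painmvpa:::frames_in_window(490, 1, 46, 70), 24L)
})

test_that("percent signal change matches its defining ratio", {
  dims <- c(4, 4, 4)
  n_frames <- 40
  data <- array(1000, c(dims, n_frames))
  t_frames <- (seq_len(n_frames) - 1) * 2
  stim <- t_frames >= 46 & t_frames < 70
  data[, , , stim] <- 1010
  run <- make_run(data)
  psc <- extract_psc_map(run, onset = 40)
  expect_equal(unique(as.vector(psc)), 1.0)
  # baseline equal to stimulus gives zero
  flat <- make_run(array(500, c(dims, n_frames)))
  expect_true(all(extract_psc_map(flat, onset = 40) == 0))
})

test_that("out-of-range windows error naming the event, zero baselines give NaN", {
  run <- make_run(array(1000, c(4, 4, 4, 40)))
  expect_error(extract_psc_map(run, onset = 10), "onset 10")
  expect_error(extract_psc_map(run, onset = 60), "onset 60")
  data <- array(1000, c(4, 4, 4, 40))
  data[1, 1, 1, ] <- 0
  run0 <- make_run(data)
  expect_warning(psc <- extract_psc_map(run0, onset = 40), "zero baseline")
  expect_true(is.nan(psc[1, 1, 1]))
  expect_false(anyNA(psc[-1]))
})

test_that("extraction is linear in the signal deviation", {
  atlas <- tiny_atlas()
  base <- extract_examples(noiseless_subject(atlas, gain = 1))
  scaled <- extract_examples(noiseless_subject(atlas, gain = 3))
  i <- which(base$label == 1)[1]
  expect_equal(scaled$psc[[i]], 3 * base$psc[[i]], tolerance = 1e-9)
})

test_that("feature mask excludes artifact voxels and only them", {
  atlas <- small_atlas(n_artifacts = 4, seed = 3)
  ex <- extract_examples(noiseless_subject(atlas))
  mask <- build_feature_mask(atlas, ex, threshold_percent = 3)
  expect_equal(mask$n_features, sum(atlas$gray) - 4L)
  expect_true(all(!mask$include[atlas$artifact_voxels]))
  # threshold Inf keeps the full gray mask
  mask_inf <- build_feature_mask(atlas, ex, threshold_percent = Inf)
  expect_equal(mask_inf$n_features, sum(atlas$gray))
  expect_equal(mask_inf$include, atlas$gray)
})

test_that("one above-threshold excursion in any training example excludes a voxel", {
  atlas <- tiny_atlas()
  ex <- extract_examples(noiseless_subject(atlas))
  vox <- which(atlas$gray)[1]
  ex$psc[[5]][vox] <- 5.0
  mask <- build_feature_mask(atlas, ex)
  expect_false(mask$include[vox])
  expect_equal(mask$n_features, sum(atlas$gray) - 1L)
})

test_that("raising the threshold never removes included voxels", {
  atlas <- tiny_atlas()
  ex <- extract_examples(simulate_subject(study_design(), atlas, seed = 4,
                                          noise_sd = 2))
  m1 <- build_feature_mask(atlas, ex, threshold_percent = 2)
  m2 <- build_feature_mask(atlas, ex, threshold_percent = 4)
  expect_true(all(m2$include[m1$include]))
})

test_that("an empty feature mask is an error", {
  atlas <- tiny_atlas()
  ex <- extract_examples(noiseless_subject(atlas))
  expect_error(build_feature_mask(atlas, ex, threshold_percent = -1), "empty")
})

test_that("vectorization preserves order and round-trips", {
  atlas <- tiny_atlas()
  ex <- extract_examples(noiseless_subject(atlas))
  mask <- build_feature_mask(atlas, ex)
  vec <- vectorize_examples(ex, mask)
  expect_equal(dim(vec$x), c(28L, mask$n_features))
  expect_equal(vec$labels, ex$label)
  expect_equal(vec$subject_ids, ex$subject_id)
  # row 7 devectorizes back to its masked map
  back <- devectorize(vec$x[7, ], mask)
  orig <- ex$psc[[7]]
  expect_equal(back[mask$feature_index], orig[mask$feature_index])
  expect_true(all(is.na(back[!mask$include])))
})

test_that("NaN inside the mask aborts vectorization with the voxel named", {
  atlas <- tiny_atlas()
  ex <- extract_examples(noiseless_subject(atlas))
  mask <- build_feature_mask(atlas, ex)
  ex$psc[[2]][mask$feature_index[5]] <- NaN
  expect_error(vectorize_examples(ex, mask), "voxel")
})
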