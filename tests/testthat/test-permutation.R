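test_that("permutations preserve per-subject class counts", {
  # 8 subjects x (14 + 14): every permutation keeps 112 + 112 overall
  labels <- rep(rep(c(1, -1), each = 14), 8)
  ids <- rep(sprintf("s%d", 1:8), each = 28)
  perms <- permute_labels(labels, ids, n_permutations = 750, seed = 4)
  expect_length(perms, 750L)
  counts <- vapply(perms, function(p) sum(p == 1), integer(1))
  expect_true(all(counts == 112L))
  per_subj <- vapply(perms[1:20], function(p) {
    all(tapply(p, ids, function(v) sum(v == 1)) == 14L)
  }, logical(1))
  expect_true(all(per_subj))
})

test_that("the permutation sequence is reproducible and seed-sensitive", {
  labels <- rep(c(1, -1), each = 6)
  ids <- rep(c("a", "b"), 6)
  p1 <- permute_labels(labels, ids, 25, seed = 7)
  p2 <- permute_labels(labels, ids, 25, seed = 7)
  expect_identical(p1, p2)
  p3 <- permute_labels(labels, ids, 25, seed = 8)
  expect_false(identical(p1, p3))
})

test_that("one subject with 2+2 examples only yields the 6 balanced arrangements", {
  labels <- c(1, 1, -1, -1)
  ids <- rep("s1", 4)
  perms <- permute_labels(labels, ids, 300, seed = 2)
  keys <- unique(vapply(perms, paste, character(1), collapse = ","))
  expect_lte(length(keys), 6L)
  expect_true(all(vapply(perms, function(p) sum(p == 1) == 2, logical(1))))
  # with enough draws all 6 arrangements appear
  expect_equal(length(keys), 6L)
})

test_that("an empty permutation set yields an empty null and errors downstream", {
  inst <- random_instance(n = 8, p = 2, seed = 3)
  null <- build_null(inst$x, list())
  expect_equal(null$n_permutations, 0L)
  m <- svm_train(inst$x, inst$y)
  mask <- list()  # not reached: the empty null errors first
  expect_error(
    significance_map(m, null, structure(list(n_features = 2), class = "feature_mask")),
    "empty"
  )
})

test_that("shuffled labels on identical rows per class yield a null centred at zero", {
  # two distinct example patterns; shuffling labels mixes them into both
  # classes, so permuted weights are symmetric about 0 and never exceed
  # the true separation
  x <- rbind(matrix(2, 10, 2), matrix(-2, 10, 2))
  y <- rep(c(1, -1), each = 10)
  true_model <- svm_train(x, y)
  perms <- permute_labels(y, rep("s", 20), 60, seed = 6)
  null <- build_null(x, perms)
  expect_equal(null$n_permutations, 60L)
  se <- stats::sd(null$weights[, 1]) / sqrt(60)
  expect_lt(abs(mean(null$weights[, 1])), 3 * se)
  expect_lte(max(abs(null$weights[, 1])),
             abs(true_model$weights[1]) + 1e-8)
})

test_that("percentile ranks and masks follow the rank definitions", {
  atlas <- null_atlas(c(6L, 6L, 6L))
  ex <- extract_examples(simulate_subject(study_design(), atlas, seed = 3))
  mask <- build_feature_mask(atlas, ex)
  nf <- mask$n_features
  n_perm <- 99
  null <- structure(
    list(
      weights = withr::with_seed(5, matrix(rnorm(n_perm * nf), n_perm, nf)),
      n_permutations = n_perm, n_failed = 0L, c_param = 10
    ),
    class = "permutation_null"
  )
  w <- numeric(nf)
  w[1] <- 100   # above every null value
  w[2] <- stats::median(null$weights[, 2])
  model <- structure(
    list(weights = w, bias = 0, c_param = 10, n_features = nf),
    class = "pain_svm"
  )
  sig <- significance_map(model, null, mask)
  i1 <- mask$feature_index[1]
  i2 <- mask$feature_index[2]
  expect_equal(sig$percentile[i1], 100)
  expect_true(sig$positive_mask_p01[i1])
  expect_false(sig$negative_mask_p01[i1])
  expect_equal(sig$percentile[i2], 100 * (49 + 0.5) / 99, tolerance = 1e-12)
  expect_false(sig$positive_mask_p01[i2] || sig$negative_mask_p01[i2] ||
                 sig$positive_mask_p10[i2] || sig$negative_mask_p10[i2])
  expect_true(all(is.na(sig$percentile[!mask$include])))
})

test_that("strict masks nest in display masks and the sides are disjoint", {
  inst <- random_instance(n = 16, p = 6, seed = 9)
  atlas <- null_atlas(c(6L, 6L, 6L))
  # synthetic mask with exactly 6 features
  include <- array(FALSE, c(6, 6, 6))
  include[1:6] <- TRUE
  mask <- structure(
    list(include = include, feature_index = which(include),
         n_features = 6L, dim = c(6L, 6L, 6L), affine = NULL,
         threshold_percent = 3),
    class = "feature_mask"
  )
  m <- svm_train(inst$x, inst$y)
  perms <- permute_labels(inst$y, rep("s", 16), 60, seed = 10)
  null <- build_null(inst$x, perms)
  sig <- significance_map(m, null, mask, alpha = 0.05, display_alpha = 0.4)
  expect_true(all(sig$positive_mask_p10[sig$positive_mask_p01]))
  expect_true(all(sig$negative_mask_p10[sig$negative_mask_p01]))
  expect_false(any(sig$positive_mask_p01 & sig$negative_mask_p01))
  expect_false(any(sig$positive_mask_p10 & sig$negative_mask_p10))
  # widening alpha never shrinks the masks
  sig2 <- significance_map(m, null, mask, alpha = 0.2, display_alpha = 0.6)
  expect_true(all(sig2$positive_mask_p01[sig$positive_mask_p01]))
  expect_true(all(sig2$negative_mask_p01[sig$negative_mask_p01]))
})

test_that("builds are deterministic and mismatched features error", {
  inst <- random_instance(n = 12, p = 3, seed = 12)
  perms <- permute_labels(inst$y, rep(c("a", "b"), 6), 15, seed = 3)
  n1 <- build_null(inst$x, perms)
  n2 <- build_null(inst$x, perms)
  expect_identical(n1$weights, n2$weights)
  m <- svm_train(inst$x, inst$y)
  bad_mask <- structure(
    list(include = array(TRUE, c(2, 2, 2)), feature_index = 1:8,
         n_features = 8L, dim = c(2L, 2L, 2L)),
    class = "feature_mask"
  )
  expect_error(significance_map(m, n1, bad_mask), "disagree")
})
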