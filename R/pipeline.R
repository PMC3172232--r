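# end-to-end study orchestration: simulate, split, extract, train, test,
# retest, confidence curve, permutation maps, ROI classifiers

#' Randomly split subjects into equal training and testing groups
#'
#' @param subject_ids Vector of subject identifiers (even count).
#' @param seed Integer seed; the split is reproducible.
#' @return List with `training` and `testing`, two disjoint id vectors
#'   covering the input.
#' @export
split_groups <- function(subject_ids, seed = 1L) {
  n <- length(subject_ids)
  if (n < 2L || n %% 2L != 0L) {
    abort("An even number (>= 2) of subjects is required for an equal split.")
  }
  training <- withr::with_seed(seed, sample(subject_ids, n / 2))
  list(
    training = sort(training),
    testing = sort(setdiff(subject_ids, training))
  )
}

#' Study configuration
#'
#' Collects every tunable of [run_study()] with the study defaults: 8
#' training + 8 testing + 8 retest subjects, C = 10, 15% confidence
#' exclusion, 750 permutations, and explicit stage-scoped seeds so the
#' simulation, the group split and the permutations can be varied
#' independently. The configuration is a plain list and round-trips
#' through serialization unchanged.
#'
#' @param design A [study_design()].
#' @param atlas A [make_atlas()] result.
#' @param n_train,n_test,n_retest Cohort sizes.
#' @param noise_sd,gain_meanlog,gain_sdlog,drift_amplitude Cohort
#'   variability parameters (see [simulate_cohort()]).
#' @param fwhm_mm Smoothing applied before extraction (default 0: the
#'   synthetic runs are generated as already-preprocessed data).
#' @param threshold_percent Artifact-exclusion threshold for the feature
#'   mask.
#' @param c_param SVM regularization constant.
#' @param exclusion_fraction Operating point of the confidence threshold.
#' @param fractions Exclusion-curve grid.
#' @param n_permutations Label permutations for the weight-map null
#'   (0 skips the significance maps).
#' @param alpha,display_alpha Two-sided significance levels for the maps.
#' @param rois ROI tibble, or `NULL` for the atlas's planted regions.
#' @param seeds Named list of integer seeds: `simulation`, `retest`,
#'   `split`, `permutation`.
#' @return An object of class `study_config` (a list).
#' @export
study_config <- function(design = study_design(),
                         atlas = make_atlas(),
                         n_train = 8L, n_test = 8L, n_retest = 8L,
                         noise_sd = 0.5, gain_meanlog = 0, gain_sdlog = 0.2,
                         drift_amplitude = 0.1,
                         fwhm_mm = 0,
                         threshold_percent = 3,
                         c_param = 10,
                         exclusion_fraction = 0.15,
                         fractions = seq(0, 0.5, by = 0.025),
                         n_permutations = 750L,
                         alpha = 0.02, display_alpha = 0.2,
                         rois = NULL,
                         seeds = list(simulation = 101L, retest = 202L,
                                      split = 303L, permutation = 404L)) {
  stopifnot(inherits(design, "pain_design"), inherits(atlas, "pain_atlas"))
  needed <- c("simulation", "retest", "split", "permutation")
  if (!all(needed %in% names(seeds))) {
    abort(sprintf("`seeds` must name: %s.", paste(needed, collapse = ", ")))
  }
  structure(
    list(
      design = design, atlas = atlas,
      n_train = n_train, n_test = n_test, n_retest = n_retest,
      noise_sd = noise_sd, gain_meanlog = gain_meanlog,
      gain_sdlog = gain_sdlog, drift_amplitude = drift_amplitude,
      fwhm_mm = fwhm_mm, threshold_percent = threshold_percent,
      c_param = c_param,
      exclusion_fraction = exclusion_fraction, fractions = fractions,
      n_permutations = n_permutations,
      alpha = alpha, display_alpha = display_alpha,
      rois = rois, seeds = seeds
    ),
    class = "study_config"
  )
}

#' Run the full cross-subject decoding study
#'
#' Simulates a training+testing cohort and an independent retest cohort,
#' randomly splits the first into equal training and testing groups,
#' builds the feature mask and trains the whole-brain SVM on the training
#' group only, then evaluates: per-subject performance on the testing and
#' retest groups, the exclusion curve and thresholded performance at the
#' configured operating fraction, voxel-weight significance maps from a
#' within-subject label-permutation null, and per-ROI classifiers.
#'
#' @param config A [study_config()].
#' @return An object of class `pain_study`: a list with `config`, `split`,
#'   `feature_mask`, `model`, `performance_test`, `performance_retest`,
#'   `curve_test`, `thresholded_test`, `thresholded_retest`,
#'   `significance` (or `NULL` when `n_permutations = 0`), `roi`,
#'   `examples_test`, `examples_retest` (decision tibbles), `counts`, and
#'   `provenance` (config hash, seeds, package and R versions).
#' @details The feature mask and the model are computed from training-group
#'   data only; an internal assertion verifies that no testing-group
#'   subject contributes to either.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  atlas <- config$atlas

  n_main <- config$n_train + config$n_test
  examples <- simulate_cohort_examples(
    n_main, design, atlas,
    seed = config$seeds$simulation,
    gain_meanlog = config$gain_meanlog, gain_sdlog = config$gain_sdlog,
    noise_sd = config$noise_sd, drift_amplitude = config$drift_amplitude,
    subject_prefix = "sub", fwhm_mm = config$fwhm_mm
  )
  ids <- unique(examples$subject_id)
  split <- split_groups(ids, seed = config$seeds$split)
  train_ex <- examples[examples$subject_id %in% split$training, ]
  test_ex <- examples[examples$subject_id %in% split$testing, ]

  # leakage guard: training-stage inputs must not contain testing subjects
  stopifnot(length(intersect(unique(train_ex$subject_id), split$testing)) == 0L)

  mask <- build_feature_mask(atlas, train_ex, config$threshold_percent)
  train_vec <- vectorize_examples(train_ex, mask)
  model <- svm_train(
    train_vec$x, train_vec$labels,
    c_param = config$c_param, mask = mask
  )

  test_vec <- vectorize_examples(test_ex, mask)
  dec_test <- svm_decide(model, test_vec$x)
  performance_test <- evaluate_predictions(
    test_vec$labels, dec_test$predicted_label, test_vec$subject_ids
  )
  curve_test <- exclusion_curve(dec_test, test_vec$labels, config$fractions)
  thresholded_test <- thresholded_performance(
    dec_test, test_vec$labels, test_vec$subject_ids, config$exclusion_fraction
  )

  retest_ex <- simulate_cohort_examples(
    config$n_retest, design, atlas,
    seed = config$seeds$retest,
    gain_meanlog = config$gain_meanlog, gain_sdlog = config$gain_sdlog,
    noise_sd = config$noise_sd, drift_amplitude = config$drift_amplitude,
    subject_prefix = "ret", fwhm_mm = config$fwhm_mm
  )
  retest_vec <- vectorize_examples(retest_ex, mask)
  dec_retest <- svm_decide(model, retest_vec$x)
  performance_retest <- evaluate_predictions(
    retest_vec$labels, dec_retest$predicted_label, retest_vec$subject_ids
  )
  thresholded_retest <- thresholded_performance(
    dec_retest, retest_vec$labels, retest_vec$subject_ids,
    config$exclusion_fraction
  )

  significance <- NULL
  if (config$n_permutations > 0) {
    perms <- permute_labels(
      train_vec$labels, train_vec$subject_ids,
      n_permutations = config$n_permutations,
      seed = config$seeds$permutation
    )
    null <- build_null(train_vec$x, perms, c_param = config$c_param)
    significance <- significance_map(
      model, null, mask,
      alpha = config$alpha, display_alpha = config$display_alpha
    )
  } else {
    warn("n_permutations = 0: skipping the weight significance maps.")
  }

  rois <- config$rois %||% default_rois(atlas)
  roi <- roi_svm_evaluate(
    train_ex, test_ex, rois, mask, c_param = config$c_param
  )

  structure(
    list(
      config = config,
      split = split,
      feature_mask = mask,
      model = model,
      performance_test = performance_test,
      performance_retest = performance_retest,
      curve_test = curve_test,
      thresholded_test = thresholded_test,
      thresholded_retest = thresholded_retest,
      significance = significance,
      roi = roi,
      decisions_test = dplyr::bind_cols(
        tibble(subject_id = test_vec$subject_ids, label = test_vec$labels),
        dec_test
      ),
      decisions_retest = dplyr::bind_cols(
        tibble(subject_id = retest_vec$subject_ids, label = retest_vec$labels),
        dec_retest
      ),
      counts = list(
        n_examples_main = nrow(examples),
        n_examples_train = nrow(train_ex),
        n_examples_test = nrow(test_ex),
        n_examples_retest = nrow(retest_ex),
        n_features = mask$n_features
      ),
      provenance = list(
        config_hash = rlang::hash(config),
        seeds = config$seeds,
        package_version = as.character(utils::packageVersion("painmvpa")),
        r_version = R.version.string
      )
    ),
    class = "pain_study"
  )
}

# metrics after excluding the least-confident fraction of a cohort's stimuli
thresholded_performance <- function(decisions, labels, subject_ids, fraction) {
  th <- apply_threshold(decisions, fraction)
  cm <- confusion_metrics(
    labels[th$kept], decisions$predicted_label[th$kept]
  )
  list(
    fraction = fraction,
    threshold = th$threshold,
    n_excluded = length(th$excluded),
    overall = cm[, c("accuracy", "ppv", "npv")],
    summary = evaluate_predictions(
      labels[th$kept], decisions$predicted_label[th$kept],
      subject_ids[th$kept]
    )
  )
}

#' @export
print.pain_study <- function(x, ...) {
  cat("<pain_study>\n")
  cat(sprintf(
    "  %d train / %d test / %d retest subjects | %d features | C = %g\n",
    x$config$n_train, x$config$n_test, x$config$n_retest,
    x$counts$n_features, x$config$c_param
  ))
  acc_t <- x$performance_test$group$mean[1]
  acc_r <- x$performance_retest$group$mean[1]
  cat(sprintf(
    "  test accuracy %.1f%% | retest %.1f%% | at %d%% exclusion: %.1f%% / %.1f%%\n",
    acc_t, acc_r, round(100 * x$config$exclusion_fraction),
    x$thresholded_test$overall$accuracy,
    x$thresholded_retest$overall$accuracy
  ))
  invisible(x)
}
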