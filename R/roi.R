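# sphere region-of-interest classifiers

#' Spherical ROI voxel mask
#'
#' Marks every voxel whose center lies within `radius_mm` of the given
#' millimeter coordinate, the functional definition of an ROI sphere.
#'
#' @param center_mm Numeric 3-vector, mm coordinates.
#' @param radius_mm Sphere radius in mm (default 8).
#' @param geometry An object carrying the grid geometry: a `pain_atlas`, a
#'   `feature_mask`, or a list with `dim` (3-vector) and `affine` (4x4).
#' @return A 3D logical array; an error if the sphere covers no voxel.
#' @examples
#' atlas <- make_atlas(seed = 1, n_artifacts = 0)
#' sum(sphere_mask(c(0, 0, 0), 8, atlas))  # 33 voxels at 4 mm
#' @export
sphere_mask <- function(center_mm, radius_mm = 8, geometry) {
  stopifnot(length(center_mm) == 3L, radius_mm > 0)
  dim3 <- geometry$dim
  affine <- geometry$affine
  if (is.null(dim3) || is.null(affine)) {
    abort("`geometry` must provide `dim` and `affine`.")
  }
  centers <- voxel_centers_mm(dim3, affine)
  d2 <- (centers[, 1] - center_mm[1])^2 + (centers[, 2] - center_mm[2])^2 +
    (centers[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2
  if (!any(inside)) {
    abort(sprintf(
      "Sphere of radius %g mm at [%s] covers no voxel of the grid.",
      radius_mm, paste(center_mm, collapse = ", ")
    ))
  }
  array(inside, dim = dim3)
}

#' Default ROI table from a synthetic atlas
#'
#' The planted region centers of the atlas, as 8 mm spheres. For real data
#' supply a tibble of previously reported coordinates instead.
#'
#' @param atlas A `pain_atlas`.
#' @param radius_mm Sphere radius (default 8).
#' @return Tibble with `name`, `x_mm`, `y_mm`, `z_mm`, `radius_mm`.
#' @export
default_rois <- function(atlas, radius_mm = 8) {
  tibble(
    name = atlas$regions$name,
    x_mm = atlas$regions$x_mm,
    y_mm = atlas$regions$y_mm,
    z_mm = atlas$regions$z_mm,
    radius_mm = radius_mm
  )
}

#' Per-ROI mean percent signal change
#'
#' For each example and each ROI, averages the percent-signal-change map
#' over the sphere's voxels intersected with the feature mask (so
#' artifact-excluded voxels are omitted). Each ROI thereby yields one
#' scalar feature per stimulus.
#'
#' @param examples Examples tibble from [extract_examples()].
#' @param rois ROI tibble as from [default_rois()].
#' @param mask A `feature_mask` (or `pain_atlas`, in which case the gray
#'   mask is used) restricting which voxels may contribute.
#' @return Numeric matrix, examples x ROIs, with ROI names as columns.
#' @export
roi_features <- function(examples, rois, mask) {
  if (inherits(mask, "pain_atlas")) {
    include <- mask$gray
    geometry <- mask
  } else if (inherits(mask, "feature_mask")) {
    include <- mask$include
    geometry <- mask
  } else {
    abort("`mask` must be a feature_mask or pain_atlas.")
  }
  n_ex <- nrow(examples)
  out <- matrix(NA_real_, n_ex, nrow(rois),
                dimnames = list(NULL, rois$name))
  for (r in seq_len(nrow(rois))) {
    sph <- sphere_mask(
      c(rois$x_mm[r], rois$y_mm[r], rois$z_mm[r]),
      rois$radius_mm[r], geometry
    )
    idx <- which(sph & include)
    if (length(idx) == 0L) {
      abort(sprintf("ROI '%s' has no voxels inside the feature mask.", rois$name[r]))
    }
    for (i in seq_len(n_ex)) {
      out[i, r] <- mean(examples$psc[[i]][idx])
    }
  }
  out
}

#' Train and test one SVM per ROI
#'
#' Mirrors the whole-brain analysis at ROI scale: for each sphere, an SVM
#' is trained on the training group's examples and evaluated per subject
#' on the testing group, using either the ROI-mean signal as a single
#' feature (default) or all sphere voxels (`voxelwise = TRUE`).
#'
#' @param train_examples,test_examples Examples tibbles from
#'   [extract_examples()].
#' @param rois ROI tibble.
#' @param mask `feature_mask` restricting contributing voxels.
#' @param c_param Regularization constant (default 10).
#' @param chance_level Chance performance percent (default 50).
#' @param voxelwise Use every sphere voxel as a feature instead of the
#'   sphere mean.
#' @return An object of class `roi_results`: `table` (one row per ROI with
#'   group means, SDs, t and p per metric, Table-style) and `summaries`
#'   (named list of `performance_summary` objects).
#' @export
roi_svm_evaluate <- function(train_examples, test_examples, rois, mask,
                             c_param = 10, chance_level = 50,
                             voxelwise = FALSE) {
  summaries <- vector("list", nrow(rois))
  names(summaries) <- rois$name
  for (r in seq_len(nrow(rois))) {
    roi <- rois[r, ]
    if (voxelwise) {
      include <- if (inherits(mask, "pain_atlas")) mask$gray else mask$include
      sph <- sphere_mask(c(roi$x_mm, roi$y_mm, roi$z_mm), roi$radius_mm, mask)
      idx <- which(sph & include)
      if (length(idx) == 0L) {
        abort(sprintf("ROI '%s' has no voxels inside the feature mask.", roi$name))
      }
      xtr <- t(vapply(train_examples$psc, function(p) p[idx],
                      numeric(length(idx))))
      xte <- t(vapply(test_examples$psc, function(p) p[idx],
                      numeric(length(idx))))
    } else {
      xtr <- roi_features(train_examples, roi, mask)
      xte <- roi_features(test_examples, roi, mask)
    }
    model <- svm_train(xtr, train_examples$label, c_param = c_param)
    dec <- svm_decide(model, xte)
    summaries[[r]] <- evaluate_predictions(
      test_examples$label, dec$predicted_label, test_examples$subject_id,
      chance_level = chance_level
    )
  }
  table <- purrr::imap_dfr(summaries, function(s, nm) {
    g <- glance(s)
    dplyr::bind_cols(tibble(region = nm), g)
  })
  structure(list(table = table, summaries = summaries), class = "roi_results")
}

#' @export
print.roi_results <- function(x, ...) {
  cat("<roi_results>\n")
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf(
      "  %-10s accuracy %5.1f +/- %4.1f (t = %.1f, p = %.2g)\n",
      tb$region[i], tb$accuracy_mean[i], tb$accuracy_sd[i],
      tb$accuracy_t[i], tb$accuracy_p[i]
    ))
  }
  invisible(x)
}

#' @export
tidy.roi_results <- function(x, ...) x$table
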