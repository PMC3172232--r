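# feature reduction: gray-matter mask intersected with artifact exclusion

#' Build the feature-inclusion mask from training examples
#'
#' A voxel becomes a feature when it lies in gray matter and its absolute
#' percent signal change stays at or below `threshold_percent` in *every*
#' training example; pain-evoked BOLD changes are below 1%, so larger
#' excursions are treated as artifacts. The mask fixes the feature order
#' (ascending linear voxel index) and is built from training data only,
#' then frozen and reapplied to test and retest examples.
#'
#' @param gray 3D logical gray-matter mask, or a `pain_atlas` (its `gray`
#'   and `affine` are used).
#' @param training_examples Examples tibble from [extract_examples()]
#'   (only the `psc` list column is used).
#' @param threshold_percent Artifact threshold in percent units (default 3;
#'   `Inf` disables artifact exclusion).
#' @return An object of class `feature_mask`: `include` (3D logical),
#'   `feature_index` (linear voxel indices in feature order),
#'   `n_features`, `dim`, `affine` (may be `NULL`), `threshold_percent`.
#' @export
build_feature_mask <- function(gray, training_examples, threshold_percent = 3) {
  affine <- NULL
  if (inherits(gray, "pain_atlas")) {
    affine <- gray$affine
    gray <- gray$gray
  }
  stopifnot(is.array(gray), length(dim(gray)) == 3L)
  include <- as.vector(gray) & TRUE
  for (psc in training_examples$psc) {
    if (!identical(dim(psc), dim(gray))) {
      abort("All examples must share the gray mask's grid.")
    }
    v <- as.vector(psc)
    ok <- !is.na(v) & abs(v) <= threshold_percent
    include <- include & ok
  }
  if (!any(include)) {
    abort("Feature mask is empty: every gray voxel was excluded.")
  }
  structure(
    list(
      include = array(include, dim = dim(gray)),
      feature_index = which(include),
      n_features = sum(include),
      dim = dim(gray),
      affine = affine,
      threshold_percent = threshold_percent
    ),
    class = "feature_mask"
  )
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf(
    "<feature_mask> %d features on a %s grid (|PSC| <= %g%%)\n",
    x$n_features, paste(x$dim, collapse = "x"), x$threshold_percent
  ))
  invisible(x)
}

#' Vectorize example maps into an examples-by-features matrix
#'
#' Rows preserve the input example order; columns follow the mask's fixed
#' feature order. Values stay in percent units with no rescaling.
#'
#' @param examples Examples tibble from [extract_examples()].
#' @param mask A [build_feature_mask()] result.
#' @return A list with `x` (matrix, examples x features), `labels` (+1/-1),
#'   `subject_ids`, `run_ids`.
#' @export
vectorize_examples <- function(examples, mask) {
  stopifnot(inherits(mask, "feature_mask"))
  x <- matrix(NA_real_, nrow(examples), mask$n_features)
  for (i in seq_len(nrow(examples))) {
    psc <- examples$psc[[i]]
    if (!identical(dim(psc), mask$dim)) {
      abort("Example grid does not match the feature mask's grid.")
    }
    x[i, ] <- psc[mask$feature_index]
  }
  bad <- which(colSums(is.na(x)) > 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-finite percent signal change inside the feature mask at %d voxel(s) (linear indices: %s).",
      length(bad),
      paste(head(mask$feature_index[bad], 10), collapse = ", ")
    ))
  }
  list(
    x = x,
    labels = examples$label,
    subject_ids = examples$subject_id,
    run_ids = examples$run_id
  )
}

#' Place a feature vector back into its 3D grid
#'
#' Inverse of the masking step of [vectorize_examples()]: voxels outside
#' the mask are `NA`.
#'
#' @param values Numeric vector of length `mask$n_features`.
#' @param mask A `feature_mask`.
#' @return A 3D array.
#' @export
devectorize <- function(values, mask) {
  stopifnot(inherits(mask, "feature_mask"), length(values) == mask$n_features)
  out <- array(NA_real_, dim = mask$dim)
  out[mask$feature_index] <- values
  out
}
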