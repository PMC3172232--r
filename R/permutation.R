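# label-permutation null for the classifier's voxel weights

#' Random label permutations
#'
#' Generates relabelings of the training examples for the permutation
#' null. By default labels are shuffled *within* each subject, respecting
#' the exchangeability structure of a multi-subject design and preserving
#' per-subject class counts; `scope = "pooled"` shuffles across the whole
#' training set instead (preserving total class counts).
#'
#' @param labels +1/-1 label vector.
#' @param subject_ids Subject identifier per example (required for
#'   within-subject permutation).
#' @param n_permutations Number of permutations (default 750).
#' @param seed Integer seed; the permutation sequence is reproducible.
#' @param scope `"within_subject"` (default) or `"pooled"`.
#' @return A list of `n_permutations` permuted label vectors.
#' @export
permute_labels <- function(labels, subject_ids = NULL, n_permutations = 750,
                           seed = 1L,
                           scope = c("within_subject", "pooled")) {
  scope <- match.arg(scope)
  if (scope == "within_subject" && is.null(subject_ids)) {
    abort("`subject_ids` is required for within-subject permutation.")
  }
  n <- length(labels)
  withr::with_seed(seed, {
    purrr::map(seq_len(max(0L, n_permutations)), function(p) {
      out <- labels
      if (scope == "pooled") {
        out <- sample(out)
      } else {
        for (s in unique(subject_ids)) {
          idx <- which(subject_ids == s)
          out[idx] <- sample(out[idx])
        }
      }
      out
    })
  })
}

#' Train the SVM under each permuted labeling
#'
#' Retrains the linear SVM once per permuted label vector, on the same
#' example matrix (the linear kernel is computed once and shared), and
#' keeps only the weight vectors; biases are discarded since the null is
#' used per voxel weight. Individual failed fits are skipped; more than 5%
#' failures aborts.
#'
#' @param x Examples matrix (examples x features).
#' @param permutations List of permuted label vectors from
#'   [permute_labels()].
#' @param c_param Regularization constant (default 10).
#' @param tol SMO stopping tolerance (looser than the real fit is fine for
#'   the null).
#' @return An object of class `permutation_null`: `weights` (matrix,
#'   permutations x features), `n_permutations`, `n_failed`, `c_param`.
#' @export
build_null <- function(x, permutations, c_param = 10, tol = 1e-6) {
  x <- as.matrix(x)
  n_perm <- length(permutations)
  if (n_perm == 0L) {
    return(structure(
      list(
        weights = matrix(numeric(0), 0, ncol(x)),
        n_permutations = 0L, n_failed = 0L, c_param = c_param
      ),
      class = "permutation_null"
    ))
  }
  K <- tcrossprod(x)
  weights <- matrix(NA_real_, n_perm, ncol(x))
  failed <- 0L
  for (p in seq_len(n_perm)) {
    y <- permutations[[p]]
    res <- tryCatch(
      {
        fit <- smo_solve(K, y, c_param, tol = tol)
        as.numeric(crossprod(x, fit$alpha * y))
      },
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed <- failed + 1L
      if (failed > 0.05 * n_perm) {
        abort(sprintf(
          "Permutation training failed for %d of %d permutations.",
          failed, n_perm
        ))
      }
    } else {
      weights[p, ] <- res
    }
  }
  if (failed > 0) weights <- weights[!is.na(weights[, 1]), , drop = FALSE]
  structure(
    list(
      weights = weights,
      n_permutations = nrow(weights),
      n_failed = failed,
      c_param = c_param
    ),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d permutations x %d features (%d failed)\n",
    x$n_permutations, ncol(x$weights), x$n_failed
  ))
  invisible(x)
}

#' Voxelwise significance of the classifier weights
#'
#' Compares each voxel's weight in the correctly labeled model against its
#' empirical null distribution of weights from permuted labelings. The
#' percentile map uses mid-ranks (`100 * (#null < w + 0.5 #null = w) /
#' n_perm`). Significance masks use the finite-sample permutation p-value
#' `(#null >= w + 1) / (n_perm + 1)` per side (and its mirror for the
#' negative side), which is exactly calibrated: at two-sided level alpha,
#' a fraction close to alpha of null voxels is flagged. Two mask pairs are
#' produced: a strict pair at `alpha` (red/blue, p < alpha/2 per side) and
#' a display pair at `display_alpha` (the 90th-percentile display
#' threshold when `display_alpha = 0.2`). No multiple-comparison
#' correction is applied.
#'
#' @param model The `pain_svm` trained on the true labels.
#' @param null A `permutation_null` on the same feature space.
#' @param mask The `feature_mask` fixing the voxel geometry.
#' @param alpha Two-sided level for the strict masks (default 0.02, i.e.
#'   p < 0.01 per side).
#' @param display_alpha Two-sided level for the display masks (default
#'   0.2, i.e. the 90th percentile per side).
#' @return An object of class `significance_map`: `percentile` (3D array,
#'   `NA` outside the mask), `positive_mask_p01`, `negative_mask_p01`
#'   (strict level), `positive_mask_p10`, `negative_mask_p10` (display
#'   level), `p_positive`, `p_negative` (3D one-sided p-value arrays),
#'   `alpha`, `display_alpha`, `n_permutations`.
#' @export
significance_map <- function(model, null, mask, alpha = 0.02,
                             display_alpha = 0.2) {
  stopifnot(inherits(model, "pain_svm"), inherits(null, "permutation_null"),
            inherits(mask, "feature_mask"))
  if (null$n_permutations == 0L) {
    abort("The permutation null is empty; significance is undefined.")
  }
  if (ncol(null$weights) != model$n_features ||
      mask$n_features != model$n_features) {
    abort("Model, null and feature mask disagree on the number of features.")
  }
  w <- model$weights
  n_perm <- null$n_permutations
  wmat <- matrix(w, n_perm, length(w), byrow = TRUE)
  n_less <- colSums(null$weights < wmat)
  n_tie <- colSums(null$weights == wmat)
  n_greater <- n_perm - n_less - n_tie

  percentile <- 100 * (n_less + 0.5 * n_tie) / n_perm
  p_pos <- (n_greater + n_tie + 1) / (n_perm + 1)
  p_neg <- (n_less + n_tie + 1) / (n_perm + 1)

  to_vol <- function(v) devectorize(v, mask)
  mask_vol <- function(flag) {
    out <- array(FALSE, dim = mask$dim)
    out[mask$feature_index] <- flag
    out
  }
  structure(
    list(
      percentile = to_vol(percentile),
      positive_mask_p01 = mask_vol(p_pos <= alpha / 2),
      negative_mask_p01 = mask_vol(p_neg <= alpha / 2),
      positive_mask_p10 = mask_vol(p_pos <= display_alpha / 2),
      negative_mask_p10 = mask_vol(p_neg <= display_alpha / 2),
      p_positive = to_vol(p_pos),
      p_negative = to_vol(p_neg),
      alpha = alpha,
      display_alpha = display_alpha,
      n_permutations = n_perm
    ),
    class = "significance_map"
  )
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf(
    "<significance_map> %d permutations | strict alpha %g: %d pos / %d neg voxels | display alpha %g: %d pos / %d neg\n",
    x$n_permutations, x$alpha,
    sum(x$positive_mask_p01), sum(x$negative_mask_p01),
    x$display_alpha,
    sum(x$positive_mask_p10), sum(x$negative_mask_p10)
  ))
  invisible(x)
}

#' @export
tidy.significance_map <- function(x, ...) {
  idx <- which(!is.na(x$percentile))
  ijk <- arrayInd(idx, dim(x$percentile))
  tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    percentile = x$percentile[idx],
    p_positive = x$p_positive[idx],
    p_negative = x$p_negative[idx],
    positive_strict = x$positive_mask_p01[idx],
    negative_strict = x$negative_mask_p01[idx]
  )
}
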