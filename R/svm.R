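# linear soft-margin SVM, solved in the dual by sequential minimal
# optimization with maximal-violating-pair working-set selection.
#
# Dual problem: min_a  1/2 a' Q a - e' a   s.t. y' a = 0, 0 <= a <= C,
# with Q_ij = y_i y_j K_ij, K the linear kernel. The bias is not
# regularized; it is recovered from the equality-constraint multiplier.

smo_solve <- function(K, y, C, tol = 1e-9, max_iter = 500000L) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)              # Q a - e at a = 0
  Kd <- diag(K)
  tau <- 1e-12
  eps_a <- 1e-12
  iter <- 0L
  gap <- Inf

  repeat {
    iter <- iter + 1L
    nyG <- -y * grad
    up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
    low <- (y < 0 & alpha < C - eps_a) | (y > 0 & alpha > eps_a)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(nyG[up])]
    gap <- nyG[i] - min(nyG[low])
    if (gap <= tol || iter > max_iter) break
    # second-order selection of j: largest decrease along the (i, j) pair
    cand <- which(low & nyG < nyG[i] - 1e-12)
    if (length(cand) == 0L) break
    b_vec <- nyG[i] - nyG[cand]
    a_vec <- Kd[i] + Kd[cand] - 2 * y[i] * y[cand] * K[cand, i]
    a_vec[a_vec <= 0] <- tau
    j <- cand[which.max(b_vec^2 / a_vec)]

    ai_old <- alpha[i]
    aj_old <- alpha[j]
    Qij <- y[i] * y[j] * K[i, j]
    if (y[i] != y[j]) {
      quad <- Kd[i] + Kd[j] + 2 * Qij
      if (quad <= 0) quad <- tau
      delta <- (-grad[i] - grad[j]) / quad
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- C - diff }
      } else {
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- C + diff }
      }
    } else {
      quad <- Kd[i] + Kd[j] - 2 * Qij
      if (quad <= 0) quad <- tau
      delta <- (grad[i] - grad[j]) / quad
      s <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (s > C) {
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- s - C }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- s }
      }
      if (s > C) {
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- s - C }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- s }
      }
    }
    dai <- alpha[i] - ai_old
    daj <- alpha[j] - aj_old
    if (dai != 0) grad <- grad + (y * y[i] * K[, i]) * dai
    if (daj != 0) grad <- grad + (y * y[j] * K[, j]) * daj
  }
  if (iter > max_iter) {
    warn(sprintf("SMO hit the iteration cap (%d); KKT gap %.3g.", max_iter, gap))
  }

  nyG <- -y * grad
  free <- alpha > eps_a & alpha < C - eps_a
  b <- if (any(free)) {
    mean(nyG[free])
  } else {
    up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
    low <- (y < 0 & alpha < C - eps_a) | (y > 0 & alpha > eps_a)
    hi <- if (any(up)) max(nyG[up]) else -Inf
    lo <- if (any(low)) min(nyG[low]) else Inf
    if (is.finite(hi) && is.finite(lo)) (hi + lo) / 2 else 0
  }
  list(alpha = alpha, bias = b, iterations = iter, kkt_gap = gap)
}

#' Train a linear soft-margin SVM
#'
#' Minimizes `1/2 ||W||^2 + C * sum(max(0, 1 - y_i (W.x_i + Z)))` over
#' weights `W` and unregularized bias `Z`, on raw feature values (no
#' standardization: the regularization constant is interpreted on the
#' percent-signal-change scale). The convex dual is solved deterministically
#' by sequential minimal optimization; `seed` is accepted for interface
#' uniformity but the solver draws no random numbers.
#'
#' @param x Numeric matrix, examples x features (percent units).
#' @param labels Numeric vector of +1/-1 class labels.
#' @param c_param Regularization constant C (default 10).
#' @param seed Ignored by the deterministic solver.
#' @param mask Optional `feature_mask` recorded on the model so voxel maps
#'   can be reconstructed from the weights.
#' @param tol Stopping tolerance on the maximal KKT violation.
#' @return An object of class `pain_svm`: `weights` (W), `bias` (Z),
#'   `c_param`, `alpha` (dual coefficients), `n_features`, `n_examples`,
#'   `objective` (primal value at the solution), `iterations`, `kkt_gap`,
#'   `mask`.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- svm_train(x, c(-1, 1))
#' m$weights  # 1
#' m$bias     # 0
#' @export
svm_train <- function(x, labels, c_param = 10, seed = NULL, mask = NULL,
                      tol = 1e-9) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  if (nrow(x) != length(labels)) abort("`x` and `labels` lengths differ.")
  if (anyNA(x) || anyNA(labels)) abort("`x` and `labels` must be free of NA.")
  if (!all(labels %in% c(-1, 1))) abort("`labels` must be +1 or -1.")
  if (length(unique(labels)) < 2L) {
    abort("Training requires examples from both classes.")
  }
  if (max(abs(sweep(x, 2, x[1, ], "-"))) == 0) {
    abort("Training examples are all identical; the classes are not distinguishable.")
  }
  stopifnot_scalar(c_param, "c_param", positive = TRUE)

  K <- tcrossprod(x)
  fit <- smo_solve(K, labels, c_param, tol = tol)
  w <- as.numeric(crossprod(x, fit$alpha * labels))

  model <- structure(
    list(
      weights = w,
      bias = fit$bias,
      c_param = c_param,
      alpha = fit$alpha,
      n_features = ncol(x),
      n_examples = nrow(x),
      iterations = fit$iterations,
      kkt_gap = fit$kkt_gap,
      mask = mask
    ),
    class = "pain_svm"
  )
  model$objective <- svm_objective(model, x, labels)
  model
}

#' Decision values and classifications for examples
#'
#' Evaluates `Y = W.X + Z` for each example row. Positive `Y` is classified
#' painful (+1); `Y <= 0`, including the boundary, is classified
#' non-painful (-1), the conservative default for a pain detector. The
#' geometric distance `|Y| / ||W||` is the confidence measure; the raw
#' functional margin `|Y|` is also reported (the two rank examples
#' identically for a fixed model).
#'
#' @param model A `pain_svm`.
#' @param x Numeric matrix (examples x features) or a single feature vector.
#' @return A tibble with one row per example: `decision_value`,
#'   `predicted_label`, `distance` (geometric), `distance_functional`.
#' @export
svm_decide <- function(model, x) {
  stopifnot(inherits(model, "pain_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    abort(sprintf(
      "Example length %d does not match the model's %d features.",
      ncol(x), model$n_features
    ))
  }
  w_norm <- sqrt(sum(model$weights^2))
  if (w_norm == 0) {
    abort("Model has a zero weight vector; distances are undefined.")
  }
  y_val <- as.numeric(x %*% model$weights + model$bias)
  tibble(
    decision_value = y_val,
    predicted_label = ifelse(y_val > 0, 1, -1),
    distance = abs(y_val) / w_norm,
    distance_functional = abs(y_val)
  )
}

#' Primal SVM objective
#'
#' `1/2 ||W||^2 + C * sum(hinge)` with `hinge_i = max(0, 1 - y_i (W.x_i + Z))`.
#' Exposed so the training optimum can be checked against independent
#' solvers and perturbed models.
#'
#' @param model A `pain_svm`, or a list with `weights`, `bias`, `c_param`.
#' @param x Examples matrix.
#' @param labels +1/-1 labels.
#' @return The objective value (a scalar).
#' @export
svm_objective <- function(model, x, labels) {
  x <- as.matrix(x)
  margins <- labels * (as.numeric(x %*% model$weights) + model$bias)
  0.5 * sum(model$weights^2) + model$c_param * sum(pmax(0, 1 - margins))
}

#' @export
print.pain_svm <- function(x, ...) {
  cat(sprintf(
    "<pain_svm> %d features, %d examples, C = %g\n  ||W|| = %.4g, Z = %.4g, objective = %.6g, %d SVs\n",
    x$n_features, x$n_examples, x$c_param,
    sqrt(sum(x$weights^2)), x$bias, x$objective,
    sum(x$alpha > 1e-8)
  ))
  invisible(x)
}

#' @rdname svm_decide
#' @param object A `pain_svm`.
#' @param newdata Examples matrix.
#' @param ... Unused.
#' @export
predict.pain_svm <- function(object, newdata, ...) {
  svm_decide(object, newdata)
}

#' Tidy a fitted linear SVM
#'
#' @param x A `pain_svm`.
#' @param ... Unused.
#' @return A tibble with one row per feature: `term` (voxel linear index
#'   when a feature mask is attached, otherwise the feature position) and
#'   `estimate` (the weight).
#' @export
tidy.pain_svm <- function(x, ...) {
  term <- if (!is.null(x$mask)) x$mask$feature_index else seq_len(x$n_features)
  tibble(term = term, estimate = x$weights)
}

#' @rdname tidy.pain_svm
#' @return For `glance()`: a one-row tibble with model-level summaries.
#' @export
glance.pain_svm <- function(x, ...) {
  tibble(
    n_features = x$n_features,
    n_examples = x$n_examples,
    n_support_vectors = sum(x$alpha > 1e-8),
    c_param = x$c_param,
    objective = x$objective,
    weight_norm = sqrt(sum(x$weights^2)),
    bias = x$bias,
    iterations = x$iterations,
    kkt_gap = x$kkt_gap
  )
}
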