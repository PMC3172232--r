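# confidence rejection: exclude the examples nearest the hyperplane

#' Exclude the least-confident fraction of examples
#'
#' Pools all decisions and drops the `floor(fraction * n)` examples with
#' the smallest geometric distance from the separating hyperplane. The
#' reported threshold is the distance of the last excluded example, so a
#' threshold derived on one cohort can be frozen and reapplied to another;
#' by default the fraction is re-derived per cohort, which makes the exact
#' threshold value cohort-specific. Ties at the threshold are broken by
#' stable input order (with a warning when every distance is equal).
#'
#' @param decisions Tibble from [svm_decide()] (a `distance` column), or a
#'   bare numeric vector of distances.
#' @param exclusion_fraction Fraction of examples to exclude, in `[0, 1)`.
#' @return A list with `kept` and `excluded` (integer index vectors that
#'   partition the input) and `threshold` (distance of the last excluded
#'   example; 0 when nothing is excluded).
#' @export
apply_threshold <- function(decisions, exclusion_fraction = 0.15) {
  d <- if (is.data.frame(decisions)) decisions$distance else as.numeric(decisions)
  if (exclusion_fraction < 0 || exclusion_fraction >= 1) {
    abort("`exclusion_fraction` must be in [0, 1).")
  }
  n <- length(d)
  k <- floor(exclusion_fraction * n)
  if (k == 0L) {
    return(list(kept = seq_len(n), excluded = integer(0), threshold = 0))
  }
  if (max(d) == min(d)) {
    warn("All distances are equal; excluding the first examples in input order.")
  }
  ord <- order(d)  # stable (radix) ordering
  excluded <- ord[seq_len(k)]
  list(
    kept = sort(ord[(k + 1):n]),
    excluded = sort(excluded),
    threshold = d[ord[k]]
  )
}

#' Performance versus fraction of stimuli excluded
#'
#' For each exclusion fraction, drops the least-confident examples (pooled
#' over all test subjects, smallest geometric distance first) and
#' recomputes accuracy, PPV and NPV on the remainder. A third-degree
#' polynomial is fitted to each metric's defined points when at least four
#' exist.
#'
#' @inheritParams apply_threshold
#' @param true_labels +1/-1 labels aligned with `decisions`.
#' @param fractions Grid of exclusion fractions in `[0, 1)`.
#' @return An object of class `exclusion_curve`: `curve` (tibble with
#'   `fraction`, `n_excluded`, `threshold`, `accuracy`, `ppv`, `npv`) and
#'   `fits` (named list of cubic coefficient vectors, `NULL` where fewer
#'   than four points are defined). The row at fraction 0 equals the
#'   unthresholded metrics.
#' @export
exclusion_curve <- function(decisions, true_labels,
                            fractions = seq(0, 0.5, by = 0.025)) {
  pred <- if (is.data.frame(decisions)) decisions$predicted_label else {
    abort("`decisions` must be a tibble from svm_decide().")
  }
  if (length(pred) != length(true_labels)) {
    abort("`decisions` and `true_labels` are not aligned.")
  }
  if (any(fractions < 0 | fractions >= 1)) {
    abort("`fractions` must lie in [0, 1).")
  }
  rows <- purrr::map_dfr(fractions, function(f) {
    th <- apply_threshold(decisions, f)
    if (length(th$kept) == 0L) abort("All examples excluded.")
    cm <- confusion_metrics(true_labels[th$kept], pred[th$kept])
    tibble(
      fraction = f, n_excluded = length(th$excluded),
      threshold = th$threshold,
      accuracy = cm$accuracy, ppv = cm$ppv, npv = cm$npv
    )
  })
  fits <- lapply(c(accuracy = "accuracy", ppv = "ppv", npv = "npv"), function(m) {
    ok <- !is.na(rows[[m]])
    if (sum(ok) >= 4L) fit_cubic(rows$fraction[ok], rows[[m]][ok]) else NULL
  })
  structure(list(curve = rows, fits = fits), class = "exclusion_curve")
}

#' Least-squares cubic fit
#'
#' Fits `y = c0 + c1 x + c2 x^2 + c3 x^3` by ordinary least squares, the
#' smoothing used for display of the exclusion curves.
#'
#' @param x,y Numeric vectors (at least 4 defined points).
#' @return Named coefficient vector `c0`..`c3` with the residual sum of
#'   squares as attribute `rss`.
#' @export
fit_cubic <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) abort("A cubic fit needs at least 4 defined points.")
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  co <- unname(coef(fit))
  structure(
    c(c0 = co[1], c1 = co[2], c2 = co[3], c3 = co[4]),
    rss = sum(fit$residuals^2)
  )
}

#' @export
print.exclusion_curve <- function(x, ...) {
  cat(sprintf(
    "<exclusion_curve> %d fractions in [%g, %g]\n",
    nrow(x$curve), min(x$curve$fraction), max(x$curve$fraction)
  ))
  print(head(x$curve, 5))
  invisible(x)
}

#' @export
tidy.exclusion_curve <- function(x, ...) x$curve

#' @export
glance.exclusion_curve <- function(x, ...) {
  at0 <- x$curve[x$curve$fraction == 0, ]
  tibble(
    n_fractions = nrow(x$curve),
    accuracy_at_0 = at0$accuracy[1],
    max_accuracy = max(x$curve$accuracy, na.rm = TRUE),
    cubic_fitted = sum(!vapply(x$fits, is.null, logical(1)))
  )
}

#' Plot an exclusion curve
#'
#' Dotted lines through the measured points, solid lines for the cubic
#' fits, one color per metric.
#'
#' @param object An `exclusion_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exclusion_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$curve,
    cols = c("accuracy", "ppv", "npv"),
    names_to = "metric", values_to = "value"
  )
  fit_lines <- purrr::imap_dfr(object$fits, function(co, m) {
    if (is.null(co)) return(NULL)
    xs <- seq(min(object$curve$fraction), max(object$curve$fraction),
              length.out = 101)
    tibble(
      metric = m, fraction = xs,
      value = co[1] + co[2] * xs + co[3] * xs^2 + co[4] * xs^3
    )
  })
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = 100 * .data$fraction, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line(linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(
      x = "stimuli excluded (%)", y = "performance (%)", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (nrow(fit_lines) > 0) {
    p <- p + ggplot2::geom_line(
      data = fit_lines,
      ggplot2::aes(x = 100 * .data$fraction, y = .data$value,
                   colour = .data$metric)
    )
  }
  p
}
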