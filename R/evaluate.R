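# per-subject and group performance metrics, t-tests against chance

#' Accuracy, PPV and NPV from paired label vectors
#'
#' Accuracy is the percent of correct classifications; PPV the percent of
#' painful predictions that were actually painful; NPV the percent of
#' non-painful predictions that were actually non-painful. PPV is `NA`
#' when nothing was predicted painful, and likewise NPV.
#'
#' @param true_labels,predicted_labels Vectors of +1/-1 labels.
#' @return A one-row tibble with `accuracy`, `ppv`, `npv` on the 0-100
#'   scale, plus the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
confusion_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) abort("No examples to score.")
  if (length(true_labels) != length(predicted_labels)) {
    abort("`true_labels` and `predicted_labels` lengths differ.")
  }
  if (!all(c(true_labels, predicted_labels) %in% c(-1, 1))) {
    abort("Labels must be +1 or -1.")
  }
  tp <- sum(true_labels == 1 & predicted_labels == 1)
  fp <- sum(true_labels == -1 & predicted_labels == 1)
  tn <- sum(true_labels == -1 & predicted_labels == -1)
  fn <- sum(true_labels == 1 & predicted_labels == -1)
  tibble(
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Metrics per subject
#'
#' @inheritParams confusion_metrics
#' @param subject_ids Subject identifier per example.
#' @return A tibble with one row per subject: `subject_id`, `accuracy`,
#'   `ppv`, `npv`, `n_examples`.
#' @export
per_subject_metrics <- function(true_labels, predicted_labels, subject_ids) {
  stopifnot(length(subject_ids) == length(true_labels))
  tibble(
    subject_id = subject_ids,
    truth = true_labels,
    pred = predicted_labels
  ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe(
      confusion_metrics(.data$truth, .data$pred)[, c("accuracy", "ppv", "npv")],
      n_examples = dplyr::n()
    )
}

#' One-sample t-test of per-subject metrics against chance
#'
#' Two-sided one-sample t-test with the usual n-1 sample SD. The balanced
#' 14 painful / 14 non-painful design puts chance at 50%.
#'
#' @param values Per-subject percentages; `NA` values are dropped.
#' @param chance_level Chance performance in percent (default 50).
#' @return One-row tibble: `mean`, `sd`, `t_statistic`, `dof`, `p_value`,
#'   `n`. With zero variance the t statistic is signed infinite (or 0 when
#'   the mean equals chance) and a note is emitted.
#' @examples
#' group_t_test(c(75, 85.7, 82.1, 100, 71.4, 96.4, 85.7, 96.4))  # t = 9.9
#' @export
group_t_test <- function(values, chance_level = 50) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("At least two non-missing values are required.")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    inform("Zero variance across subjects; t statistic is degenerate.")
    t_stat <- if (m == chance_level) 0 else sign(m - chance_level) * Inf
    p <- if (m == chance_level) 1 else 0
  } else {
    t_stat <- (m - chance_level) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble(
    mean = m, sd = if (n > 1) s else NA_real_,
    t_statistic = t_stat, dof = n - 1L, p_value = p, n = n
  )
}

#' Group performance summary
#'
#' Summarizes per-subject accuracy/PPV/NPV with group means, SDs (n-1) and
#' two-sided one-sample t-tests against chance. Metrics undefined for a
#' subject (e.g. PPV with no painful predictions) are `NA` and excluded
#' pairwise. A metric is flagged significant at p < 0.05.
#'
#' @param per_subject Tibble with columns `subject_id`, `accuracy`, `ppv`,
#'   `npv` (as from [per_subject_metrics()]).
#' @param chance_level Chance performance in percent (default 50).
#' @return An object of class `performance_summary` with elements
#'   `per_subject`, `group` (one row per metric: mean, sd, t, dof, p,
#'   significant) and `chance_level`.
#' @export
summarize_group <- function(per_subject, chance_level = 50) {
  stopifnot(all(c("subject_id", "accuracy", "ppv", "npv") %in% names(per_subject)))
  if (nrow(per_subject) < 1L) abort("At least one subject is required.")
  one <- function(metric) {
    v <- per_subject[[metric]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n >= 2L) {
      tt <- group_t_test(v, chance_level)
      tibble(
        metric = metric, mean = tt$mean, sd = tt$sd,
        t_statistic = tt$t_statistic, dof = tt$dof, p_value = tt$p_value,
        n = n, significant = tt$p_value < 0.05
      )
    } else {
      tibble(
        metric = metric, mean = if (n == 1) v else NA_real_, sd = NA_real_,
        t_statistic = NA_real_, dof = NA_integer_, p_value = NA_real_,
        n = n, significant = NA
      )
    }
  }
  group <- dplyr::bind_rows(lapply(c("accuracy", "ppv", "npv"), one))
  structure(
    list(
      per_subject = as_tibble(per_subject),
      group = group,
      chance_level = chance_level
    ),
    class = "performance_summary"
  )
}

#' Score predictions and summarize by subject in one step
#'
#' @inheritParams per_subject_metrics
#' @inheritParams summarize_group
#' @return A `performance_summary`.
#' @export
evaluate_predictions <- function(true_labels, predicted_labels, subject_ids,
                                 chance_level = 50) {
  summarize_group(
    per_subject_metrics(true_labels, predicted_labels, subject_ids),
    chance_level = chance_level
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance_summary> %d subjects (chance %g%%)\n",
    nrow(x$per_subject), x$chance_level
  ))
  g <- x$group
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %-8s %5.1f +/- %4.1f %s (t(%d) = %.1f, p = %.2g)\n",
      g$metric[i], g$mean[i], g$sd[i],
      ifelse(isTRUE(g$significant[i]), "*", " "),
      g$dof[i], g$t_statistic[i], g$p_value[i]
    ))
  }
  invisible(x)
}

#' Tidy a performance summary
#'
#' @param x A `performance_summary`.
#' @param ... Unused.
#' @return `tidy()` returns the per-subject metric tibble; `glance()` a
#'   one-row tibble of group means, SDs, t statistics and p-values.
#' @export
tidy.performance_summary <- function(x, ...) x$per_subject

#' @rdname tidy.performance_summary
#' @export
glance.performance_summary <- function(x, ...) {
  g <- x$group
  out <- tibble(.rows = 1)
  for (i in seq_len(nrow(g))) {
    out[[paste0(g$metric[i], "_mean")]] <- g$mean[i]
    out[[paste0(g$metric[i], "_sd")]] <- g$sd[i]
    out[[paste0(g$metric[i], "_t")]] <- g$t_statistic[i]
    out[[paste0(g$metric[i], "_p")]] <- g$p_value[i]
  }
  out$n_subjects <- nrow(x$per_subject)
  out$chance_level <- x$chance_level
  out
}

#' Plot per-subject performance
#'
#' Bar chart of per-subject accuracy/PPV/NPV with the chance level marked.
#'
#' @param object A `performance_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.performance_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_subject,
    cols = c("accuracy", "ppv", "npv"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$subject_id, y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(
      yintercept = object$chance_level, linetype = "dashed"
    ) +
    ggplot2::labs(x = "subject", y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
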