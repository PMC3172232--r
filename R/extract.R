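# percent-signal-change example extraction from block-design runs

# 1-based frame indices whose acquisition onset time falls in [start, end)
frames_in_window <- function(n_frames, tr, start, end) {
  t_frames <- (seq_len(n_frames) - 1) * tr
  which(t_frames >= start & t_frames < end)
}

#' Extract a percent-signal-change map for one stimulus
#'
#' Computes, per voxel, `100 * (stimulus mean - baseline mean) / baseline
#' mean`. The baseline window is the `baseline_seconds` (default 20 s)
#' immediately preceding stimulus onset; the stimulus window excludes the
#' first `rise_seconds` (default 6 s) of the heat block, allowing the BOLD
#' response to reach its plateau, and runs to the end of the block. A frame
#' belongs to a window when its acquisition onset time lies in the
#' half-open interval `[start, end)`; at TR = 2 s the windows hold exactly
#' 10 baseline and 12 stimulus frames.
#'
#' @param run A `bold_run`.
#' @param onset Stimulus onset, seconds from run start.
#' @param duration Stimulus duration, seconds (default 30).
#' @param baseline_seconds Length of the pre-stimulus baseline window.
#' @param rise_seconds Initial portion of the block excluded from the
#'   stimulus window.
#' @return A 3D array of percent signal change. Voxels whose baseline mean
#'   is zero are set to `NaN` and reported with a warning.
#' @export
extract_psc_map <- function(run, onset, duration = 30,
                            baseline_seconds = 20, rise_seconds = 6) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  n_frames <- d[4]
  tr <- run$tr_seconds
  run_end <- n_frames * tr
  if (onset - baseline_seconds < 0 || onset + duration > run_end) {
    abort(sprintf(
      "Event at onset %g s: windows [%g, %g) and [%g, %g) must lie inside the run [0, %g).",
      onset, onset - baseline_seconds, onset, onset + rise_seconds,
      onset + duration, run_end
    ))
  }
  base_idx <- frames_in_window(n_frames, tr, onset - baseline_seconds, onset)
  stim_idx <- frames_in_window(n_frames, tr, onset + rise_seconds, onset + duration)

  mat <- run$data
  dim(mat) <- c(prod(d[1:3]), n_frames)
  base_mean <- rowMeans(mat[, base_idx, drop = FALSE])
  stim_mean <- rowMeans(mat[, stim_idx, drop = FALSE])
  zero <- base_mean == 0
  if (any(zero)) {
    warn(sprintf(
      "%d voxel(s) with zero baseline mean set to NaN (first: %d).",
      sum(zero), which(zero)[1]
    ))
  }
  psc <- 100 * (stim_mean - base_mean) / base_mean
  psc[zero] <- NaN
  array(psc, dim = d[1:3])
}

#' Extract all example maps from a run or subject
#'
#' Applies [extract_psc_map()] to every event, returning one row per
#' stimulus with its percent-signal-change map and metadata. Class labels
#' are +1 for the positive (painful) condition and -1 otherwise.
#'
#' @param x A `bold_run` or `pain_subject`.
#' @param positive_class Condition label mapped to +1 (default "painful").
#' @inheritParams extract_psc_map
#' @return A tibble with columns `subject_id`, `run_id`, `stimulus_index`
#'   (within subject), `condition`, `label` (+1/-1) and `psc` (list column
#'   of 3D arrays).
#' @export
extract_examples <- function(x, positive_class = "painful",
                             baseline_seconds = 20, rise_seconds = 6) {
  if (inherits(x, "pain_subject")) {
    out <- purrr::map_dfr(
      x$runs, extract_examples,
      positive_class = positive_class,
      baseline_seconds = baseline_seconds, rise_seconds = rise_seconds
    )
    out$stimulus_index <- seq_len(nrow(out))
    return(out)
  }
  stopifnot(inherits(x, "bold_run"))
  ev <- x$events
  maps <- purrr::map2(
    ev$onset, ev$duration,
    function(onset, duration) {
      extract_psc_map(
        x, onset, duration,
        baseline_seconds = baseline_seconds, rise_seconds = rise_seconds
      )
    }
  )
  tibble(
    subject_id = x$subject_id %||% NA_character_,
    run_id = x$run_id %||% NA_character_,
    stimulus_index = seq_len(nrow(ev)),
    condition = ev$trial_type,
    label = ifelse(ev$trial_type == positive_class, 1, -1),
    psc = maps
  )
}

#' Simulate a cohort and extract its examples, one subject at a time
#'
#' Streaming equivalent of `simulate_cohort()` followed by
#' [extract_examples()]: each subject's raw runs are simulated, optionally
#' smoothed, reduced to percent-signal-change example maps, and discarded
#' before the next subject is touched, keeping memory proportional to one
#' subject. The result is example-for-example identical to the batch path
#' under the same seed.
#'
#' @inheritParams simulate_cohort
#' @param fwhm_mm Spatial smoothing applied to each run before extraction
#'   (0, the default, skips smoothing: synthetic runs are generated as
#'   already-preprocessed data).
#' @inheritParams extract_examples
#' @return A tibble of examples as in [extract_examples()].
#' @export
simulate_cohort_examples <- function(n_subjects, design, atlas, seed = 1L,
                                     gain_meanlog = 0, gain_sdlog = 0.2,
                                     noise_sd = 0.5, drift_amplitude = 0.1,
                                     hrf = c("boxcar", "gamma"),
                                     subject_prefix = "sub",
                                     fwhm_mm = 0,
                                     positive_class = NULL) {
  hrf <- match.arg(hrf)
  positive_class <- positive_class %||% design$conditions[1]
  params <- cohort_params(
    n_subjects, seed, gain_meanlog, gain_sdlog,
    noise_sd, drift_amplitude, subject_prefix
  )
  purrr::pmap_dfr(params, function(subject_id, gain, noise_sd, drift_amplitude, seed) {
    subj <- simulate_subject(
      design, atlas,
      subject_id = subject_id, gain = gain, noise_sd = noise_sd,
      drift_amplitude = drift_amplitude, seed = seed, hrf = hrf
    )
    if (fwhm_mm > 0) {
      subj$runs <- purrr::map(subj$runs, smooth_volume, fwhm_mm = fwhm_mm)
    }
    extract_examples(subj, positive_class = positive_class)
  })
}
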