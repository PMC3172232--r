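# synthetic BOLD run and cohort simulation

# sampled activation time course for one run: 1 inside the effective
# stimulus window of each block, 0 elsewhere. The boxcar is delayed 6 s
# relative to stimulus onset, consistent with the rise allowance of the
# extraction window, so a noiseless run round-trips planted amplitudes
# exactly. The gamma option convolves the stimulus indicator with a gamma
# hemodynamic response (peak ~6 s), rescaled to unit peak.
activation_course <- function(design, hrf = c("boxcar", "gamma")) {
  hrf <- match.arg(hrf)
  t_frames <- (seq_len(design$volumes_per_run) - 1) * design$tr_seconds
  a <- numeric(length(t_frames))
  if (hrf == "boxcar") {
    for (onset in design$onsets_s) {
      a[t_frames >= onset + 6 & t_frames < onset + design$stimulus_seconds] <- 1
    }
  } else {
    stim <- numeric(length(t_frames))
    for (onset in design$onsets_s) {
      stim[t_frames >= onset & t_frames < onset + design$stimulus_seconds] <- 1
    }
    tt <- seq(0, 30, by = design$tr_seconds)
    shape <- 6 / 0.9
    h <- stats::dgamma(tt, shape = shape, scale = 0.9)
    h <- h / max(h)
    a <- stats::convolve(stim, rev(h), type = "open")[seq_along(stim)]
    a <- a / max(a)
  }
  a
}

#' Simulate one subject's preprocessed BOLD runs
#'
#' Generates `2 * runs_per_condition` block-design runs on the atlas grid.
#' Every voxel time series is
#' `baseline * (1 + gain * effect/100 * a(t) + drift(t) + noise)`, where
#' `a(t)` is the activation time course (delayed boxcar by default),
#' `effect` is the condition's planted percent-signal-change map, `drift` is
#' a linear trend spanning `drift_amplitude` percent over the run, and
#' `noise` is i.i.d. Gaussian with SD `noise_sd` percent per voxel-frame.
#' Runs alternate painful / non-painful starting with painful.
#'
#' @param design A [study_design()].
#' @param atlas A [make_atlas()] result.
#' @param subject_id Subject identifier string.
#' @param gain Per-subject multiplicative amplitude factor.
#' @param noise_sd Noise SD, percent of baseline, per voxel-frame.
#' @param drift_amplitude Peak-to-peak linear drift over a run, percent.
#' @param seed Integer seed; identical seeds and parameters give
#'   bit-identical volumes.
#' @param hrf `"boxcar"` (default) or `"gamma"`.
#' @param baseline_intensity Baseline image intensity, arbitrary units.
#' @return A `pain_subject`: list with `subject_id`, `runs` (list of
#'   `bold_run`: 4D `data`, `affine`, `tr_seconds`, `events` tibble with
#'   BIDS-style `onset`/`duration`/`trial_type` columns, `condition`,
#'   `run_id`), and the simulation parameters.
#' @export
simulate_subject <- function(design, atlas, subject_id = "sub-01",
                             gain = 1, noise_sd = 0.5,
                             drift_amplitude = 0.1, seed = 1L,
                             hrf = c("boxcar", "gamma"),
                             baseline_intensity = 1000) {
  stopifnot(inherits(design, "pain_design"), inherits(atlas, "pain_atlas"))
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  hrf <- match.arg(hrf)

  a <- activation_course(design, hrf)
  t_frames <- (seq_len(design$volumes_per_run) - 1) * design$tr_seconds
  drift <- (drift_amplitude / 100) * (t_frames / design$run_seconds - 0.5)
  n_vox <- prod(atlas$dim)
  n_frames <- design$volumes_per_run

  conditions <- rep(design$conditions, times = design$runs_per_condition)
  run_seeds <- derive_seeds(seed, length(conditions))

  runs <- vector("list", length(conditions))
  for (r in seq_along(conditions)) {
    cond <- conditions[r]
    effect <- if (cond == design$conditions[1]) atlas$effect_pain else atlas$effect_nonpain
    signal <- outer(as.vector(effect) * gain / 100, a)  # n_vox x n_frames
    signal <- sweep(signal, 2, drift, "+")
    if (noise_sd > 0) {
      noise <- withr::with_seed(
        run_seeds[r],
        matrix(rnorm(n_vox * n_frames, sd = noise_sd / 100), n_vox, n_frames)
      )
      signal <- signal + noise
    }
    vol <- baseline_intensity * (1 + signal)
    dim(vol) <- c(atlas$dim, n_frames)
    runs[[r]] <- structure(
      list(
        data = vol,
        affine = atlas$affine,
        tr_seconds = design$tr_seconds,
        events = design_events(design, cond),
        condition = cond,
        run_id = sprintf("run-%02d", r),
        subject_id = subject_id
      ),
      class = "bold_run"
    )
  }

  structure(
    list(
      subject_id = subject_id,
      runs = runs,
      gain = gain,
      noise_sd = noise_sd,
      drift_amplitude = drift_amplitude,
      seed = seed
    ),
    class = "pain_subject"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf(
    "<bold_run %s %s> %s volumes, TR %g s, condition %s\n",
    x$subject_id, x$run_id,
    paste(dim(x$data), collapse = "x"), x$tr_seconds, x$condition
  ))
  invisible(x)
}

# per-subject simulation parameters for a cohort, drawn once from the cohort
# seed so batch and streaming simulation agree example-for-example
cohort_params <- function(n_subjects, seed,
                          gain_meanlog = 0, gain_sdlog = 0.2,
                          noise_sd = 0.5, drift_amplitude = 0.1,
                          subject_prefix = "sub") {
  stopifnot(n_subjects >= 1)
  draws <- withr::with_seed(seed, list(
    gain = stats::rlnorm(n_subjects, gain_meanlog, gain_sdlog),
    seed = sample.int(.Machine$integer.max - 1L, n_subjects)
  ))
  tibble(
    subject_id = sprintf("%s-%02d", subject_prefix, seq_len(n_subjects)),
    gain = draws$gain,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    seed = draws$seed
  )
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject gains from a log-normal distribution
#' (`gain ~ lognormal(meanlog, sdlog)`) and simulates each subject with its
#' own derived seed, so the cohort is reproducible from the single `seed`
#' and a subject simulated on its own with the same derived seed is
#' bit-identical.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @inheritParams simulate_subject
#' @param gain_meanlog,gain_sdlog Log-normal parameters of the per-subject
#'   gain (defaults 0 and 0.2).
#' @param subject_prefix Prefix for subject identifiers.
#' @return List of `pain_subject` objects.
#' @details A 16-subject cohort at the default grid holds roughly 5 GB of
#'   raw volumes. For whole-cohort processing prefer
#'   [simulate_cohort_examples()], which streams one subject at a time and
#'   keeps only the extracted example maps.
#' @export
simulate_cohort <- function(n_subjects, design, atlas, seed = 1L,
                            gain_meanlog = 0, gain_sdlog = 0.2,
                            noise_sd = 0.5, drift_amplitude = 0.1,
                            hrf = c("boxcar", "gamma"),
                            subject_prefix = "sub") {
  hrf <- match.arg(hrf)
  params <- cohort_params(
    n_subjects, seed, gain_meanlog, gain_sdlog,
    noise_sd, drift_amplitude, subject_prefix
  )
  purrr::pmap(params, function(subject_id, gain, noise_sd, drift_amplitude, seed) {
    simulate_subject(
      design, atlas,
      subject_id = subject_id, gain = gain, noise_sd = noise_sd,
      drift_amplitude = drift_amplitude, seed = seed, hrf = hrf
    )
  })
}
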