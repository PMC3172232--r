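#' Block-design study parameters
#'
#' Describes the thermal block design: every stimulation block is a long
#' baseline period at a neutral temperature followed by a heat plateau, with
#' one percent-signal-change example extracted per block. Defaults reproduce
#' the study timing: TR 2 s, 40 s baseline + 30 s heat, 7 blocks per run,
#' 2 runs per condition, so each subject contributes 14 painful and 14
#' non-painful examples.
#'
#' @param tr_seconds Repetition time of the BOLD series, seconds.
#' @param baseline_seconds Baseline period before each heat plateau, seconds.
#' @param stimulus_seconds Duration of the heat plateau, seconds.
#' @param blocks_per_run Number of baseline+heat blocks per run.
#' @param runs_per_condition Number of runs per condition.
#' @param conditions Ordered pair of condition labels; the first is the
#'   positive (painful) class.
#'
#' @return An object of class `pain_design`: a list with the arguments plus
#'   `block_seconds`, `run_seconds`, `volumes_per_run`,
#'   `stimuli_per_condition` (per subject), and `onsets_s`, the block onset
#'   times within a run (seconds from run start, so the first baseline period
#'   precedes the first onset).
#'
#' @details The run must tile into an integer number of volumes:
#'   `blocks_per_run * (baseline_seconds + stimulus_seconds) / tr_seconds`
#'   must be a whole number, otherwise an error is raised.
#'
#' @examples
#' d <- study_design()
#' d$volumes_per_run      # 245
#' d$stimuli_per_condition # 14
#' @export
study_design <- function(tr_seconds = 2,
                         baseline_seconds = 40,
                         stimulus_seconds = 30,
                         blocks_per_run = 7L,
                         runs_per_condition = 2L,
                         conditions = c("painful", "nonpainful")) {
  stopifnot_scalar(tr_seconds, "tr_seconds", positive = TRUE)
  stopifnot_scalar(baseline_seconds, "baseline_seconds", positive = TRUE)
  stopifnot_scalar(stimulus_seconds, "stimulus_seconds", positive = TRUE)
  stopifnot_scalar(blocks_per_run, "blocks_per_run", positive = TRUE)
  stopifnot_scalar(runs_per_condition, "runs_per_condition", positive = TRUE)
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    abort("`conditions` must be two distinct labels (painful first).")
  }

  block_seconds <- baseline_seconds + stimulus_seconds
  run_seconds <- blocks_per_run * block_seconds
  n_vol <- run_seconds / tr_seconds
  if (abs(n_vol - round(n_vol)) > 1e-9) {
    abort(sprintf(
      "Run length %.6g s is not a whole number of volumes at TR = %.6g s (%.6g).",
      run_seconds, tr_seconds, n_vol
    ))
  }

  onsets <- baseline_seconds + (seq_len(blocks_per_run) - 1) * block_seconds
  structure(
    list(
      tr_seconds = tr_seconds,
      baseline_seconds = baseline_seconds,
      stimulus_seconds = stimulus_seconds,
      blocks_per_run = as.integer(blocks_per_run),
      runs_per_condition = as.integer(runs_per_condition),
      conditions = conditions,
      block_seconds = block_seconds,
      run_seconds = run_seconds,
      volumes_per_run = as.integer(round(n_vol)),
      stimuli_per_condition = as.integer(blocks_per_run * runs_per_condition),
      onsets_s = onsets
    ),
    class = "pain_design"
  )
}

#' @export
print.pain_design <- function(x, ...) {
  cat("<pain_design>\n")
  cat(sprintf(
    "  TR %.3g s | %g s baseline + %g s heat x %d blocks x %d runs/condition\n",
    x$tr_seconds, x$baseline_seconds, x$stimulus_seconds,
    x$blocks_per_run, x$runs_per_condition
  ))
  cat(sprintf(
    "  %d volumes/run | %d + %d stimuli per subject (%s, %s)\n",
    x$volumes_per_run, x$stimuli_per_condition, x$stimuli_per_condition,
    x$conditions[1], x$conditions[2]
  ))
  invisible(x)
}

#' Event table for one run
#'
#' BIDS-style events (onset, duration, trial_type), seconds from run start.
#'
#' @param design A [study_design()].
#' @param condition One of `design$conditions`.
#' @return A tibble with columns `onset`, `duration`, `trial_type`.
#' @export
design_events <- function(design, condition) {
  stopifnot(inherits(design, "pain_design"))
  condition <- match.arg(condition, design$conditions)
  tibble(
    onset = design$onsets_s,
    duration = design$stimulus_seconds,
    trial_type = condition
  )
}
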