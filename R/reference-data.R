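#' Published per-subject performance of the whole-brain pain classifier
#'
#' Per-subject accuracy, positive predictive value and negative predictive
#' value reported for the original cross-subject pain-decoding experiment:
#' eight subjects in the held-out testing group (`"test"`) and eight in
#' the independent retest group (`"retest"`), each receiving 14 painful
#' and 14 non-painful heat stimuli. These printed values are shipped so
#' the group-summary arithmetic (means, SDs, one-sample t-tests against
#' 50% chance) can be validated against the published group rows without
#' any imaging data.
#'
#' @param cohort `"test"` or `"retest"`.
#' @return A tibble with columns `subject_id`, `accuracy`, `ppv`, `npv`
#'   (percent).
#' @examples
#' summarize_group(reference_performance("test"))   # mean accuracy 86.6
#' summarize_group(reference_performance("retest")) # mean accuracy 74.6
#' @export
reference_performance <- function(cohort = c("test", "retest")) {
  cohort <- match.arg(cohort)
  if (cohort == "test") {
    tibble(
      subject_id = sprintf("test-%02d", 1:8),
      accuracy = c(75.0, 85.7, 82.1, 100.0, 71.4, 96.4, 85.7, 96.4),
      ppv = c(100, 91.7, 80.0, 100.0, 71.4, 93.3, 85.7, 100),
      npv = c(66.7, 81.2, 84.6, 100, 71.4, 100, 85.7, 93.3)
    )
  } else {
    tibble(
      subject_id = sprintf("retest-%02d", 1:8),
      accuracy = c(64.3, 85.7, 64.3, 71.4, 67.9, 92.9, 60.7, 89.3),
      ppv = c(66.7, 77.8, 70.0, 100.0, 66.7, 87.5, 100.0, 100.0),
      npv = c(62.5, 100.0, 61.1, 63.6, 69.2, 100.0, 56.0, 82.4)
    )
  }
}
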