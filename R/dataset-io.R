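# dataset directory export / import: NIfTI runs, TSV events, JSON manifest

nifti_with_affine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_sizes(affine), 1)[seq_len(length(dim(arr)))]
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write a cohort to a dataset directory
#'
#' Lays out one NIfTI volume and one BIDS-style TSV event file per run
#' (`sub-XX/sub-XX_run-YY_bold.nii.gz`, `..._events.tsv`), the gray-matter
#' mask, and a JSON manifest describing subjects, runs and conditions.
#' Events and manifest metadata round-trip bit-identically through
#' [read_dataset()].
#'
#' @param cohort List of `pain_subject` objects (from [simulate_cohort()]).
#' @param directory Output directory (created if needed).
#' @param atlas The `pain_atlas` whose gray mask and affine apply.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
write_dataset <- function(cohort, directory, atlas) {
  stopifnot(inherits(atlas, "pain_atlas"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort(sprintf("Cannot create dataset directory '%s'.", directory))
  }
  subjects <- list()
  for (subj in cohort) {
    sub_dir <- file.path(directory, subj$subject_id)
    dir.create(sub_dir, showWarnings = FALSE)
    runs <- list()
    for (run in subj$runs) {
      stem <- sprintf("%s_%s", subj$subject_id, run$run_id)
      bold_path <- file.path(sub_dir, paste0(stem, "_bold.nii.gz"))
      events_path <- file.path(sub_dir, paste0(stem, "_events.tsv"))
      RNifti::writeNifti(nifti_with_affine(run$data, run$affine), bold_path)
      utils::write.table(
        run$events, events_path,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      runs[[run$run_id]] <- list(
        run_id = run$run_id,
        condition = run$condition,
        bold = file.path(subj$subject_id, basename(bold_path)),
        events = file.path(subj$subject_id, basename(events_path))
      )
    }
    subjects[[subj$subject_id]] <- list(
      subject_id = subj$subject_id,
      gain = subj$gain,
      noise_sd = subj$noise_sd,
      runs = unname(runs)
    )
  }
  RNifti::writeNifti(
    nifti_with_affine(atlas$gray * 1, atlas$affine),
    file.path(directory, "gray_mask.nii.gz")
  )
  manifest <- list(
    n_subjects = length(cohort),
    tr_seconds = cohort[[1]]$runs[[1]]$tr_seconds,
    conditions = unique(vapply(
      cohort[[1]]$runs, function(r) r$condition, character(1)
    )),
    gray_mask = "gray_mask.nii.gz",
    subjects = unname(subjects)
  )
  jsonlite::write_json(
    manifest, file.path(directory, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Read a dataset directory back
#'
#' @param directory A directory written by [write_dataset()].
#' @return A list with `subjects` (list of `pain_subject`), `gray`
#'   (3D logical), `affine`, and the parsed `manifest`.
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json under '%s'.", directory))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  mask_img <- RNifti::readNifti(file.path(directory, manifest$gray_mask))
  gray <- as.array(mask_img) > 0
  affine <- unclass(RNifti::xform(mask_img))[1:4, 1:4]
  subjects <- purrr::map(manifest$subjects, function(s) {
    runs <- purrr::map(s$runs, function(r) {
      img <- RNifti::readNifti(file.path(directory, r$bold))
      data <- as.array(img)
      attributes(data) <- list(dim = dim(data))
      events <- utils::read.delim(
        file.path(directory, r$events),
        colClasses = c("numeric", "numeric", "character")
      )
      structure(
        list(
          data = data,
          affine = unclass(RNifti::xform(img))[1:4, 1:4],
          tr_seconds = manifest$tr_seconds,
          events = as_tibble(events),
          condition = r$condition,
          run_id = r$run_id,
          subject_id = s$subject_id
        ),
        class = "bold_run"
      )
    })
    structure(
      list(
        subject_id = s$subject_id,
        runs = runs,
        gain = s$gain,
        noise_sd = s$noise_sd
      ),
      class = "pain_subject"
    )
  })
  list(subjects = subjects, gray = gray, affine = affine, manifest = manifest)
}

#' Write a significance map's volumes as NIfTI
#'
#' @param sig A `significance_map`.
#' @param directory Output directory.
#' @param affine 4x4 affine for the grid (e.g. the atlas affine).
#' @return Invisibly, the written file paths.
#' @export
write_significance_maps <- function(sig, directory, affine) {
  stopifnot(inherits(sig, "significance_map"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  vols <- list(
    percentile = sig$percentile,
    positive_mask_p01 = sig$positive_mask_p01 * 1,
    negative_mask_p01 = sig$negative_mask_p01 * 1,
    positive_mask_p10 = sig$positive_mask_p10 * 1,
    negative_mask_p10 = sig$negative_mask_p10 * 1
  )
  paths <- character(0)
  for (nm in names(vols)) {
    v <- vols[[nm]]
    v[is.na(v)] <- 0
    p <- file.path(directory, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(nifti_with_affine(v, affine), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
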