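#' Default planted effect regions
#'
#' Three spherical effect regions emulating canonical pain-processing
#' anatomy at MNI-like coordinates: a left mid-insula and a right secondary
#' somatosensory sphere that respond more strongly to painful heat
#' (pain-predictive), and a left primary-motor sphere that responds more
#' strongly to non-painful warmth (nonpain-predictive). Amplitudes are in
#' percent-signal-change units and stay below 1%, matching the magnitude of
#' pain-evoked BOLD responses.
#'
#' @return A tibble with columns `name`, `x_mm`, `y_mm`, `z_mm`, `radius_mm`,
#'   `amplitude_pain`, `amplitude_nonpain`.
#' @export
default_regions <- function() {
  tibble(
    name = c("insula_L", "S2_R", "M1_L"),
    x_mm = c(-36, 36, -40),
    y_mm = c(0, -16, -12),
    z_mm = c(12, 20, 36),
    radius_mm = 8,
    amplitude_pain = c(0.5, 0.5, 0.1),
    amplitude_nonpain = c(0.1, 0.1, 0.5)
  )
}

#' Build a synthetic brain atlas with planted effects
#'
#' Constructs the spatial scaffolding for the synthetic cohorts: an
#' ellipsoidal gray-matter mask on a regular grid with an MNI-like affine,
#' voxelwise percent-signal-change effect maps for the painful and
#' non-painful conditions (constant inside each region sphere, zero
#' outside), and a small set of randomly placed artifact voxels whose
#' apparent signal change exceeds the 3% plausibility bound, so the
#' artifact-exclusion filter has something real to remove.
#'
#' @param grid_shape Integer 3-vector of voxel counts (default `c(32, 38, 32)`,
#'   a desk-scale stand-in for a normalized whole-brain grid).
#' @param voxel_mm Isotropic voxel size in mm (default 4).
#' @param regions Tibble of effect regions as in [default_regions()].
#' @param seed Integer seed controlling artifact-voxel placement.
#' @param n_artifacts Number of artifact voxels planted in gray matter
#'   outside the effect regions (default 5).
#' @param artifact_amplitude Apparent percent signal change of artifact
#'   voxels, applied in both conditions (default 5).
#' @param gray_axes_frac Semi-axes of the gray-matter ellipsoid as a
#'   fraction of each grid extent (default 0.45).
#'
#' @return An object of class `pain_atlas`: gray mask (3D logical),
#'   `effect_pain` and `effect_nonpain` (3D, percent units), `affine`,
#'   `dim`, `voxel_mm`, the `regions` tibble augmented with voxel counts and
#'   a derived `sign` column (+1 pain-predictive, -1 nonpain-predictive),
#'   `region_voxels` (list of linear voxel indices per region) and
#'   `artifact_voxels` (linear indices).
#' @examples
#' atlas <- make_atlas(seed = 1)
#' sum(atlas$gray)                    # gray-matter voxel count
#' atlas$regions$n_voxels             # 33 voxels per 8 mm sphere at 4 mm
#' @export
make_atlas <- function(grid_shape = c(32L, 38L, 32L),
                       voxel_mm = 4,
                       regions = default_regions(),
                       seed = 1L,
                       n_artifacts = 5L,
                       artifact_amplitude = 5,
                       gray_axes_frac = 0.45) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  stopifnot_scalar(voxel_mm, "voxel_mm", positive = TRUE)
  grid_shape <- as.integer(grid_shape)

  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * floor(grid_shape / 2)

  centers <- voxel_centers_mm(grid_shape, affine)

  # ellipsoidal gray-matter "brain", centered on the grid
  mid <- voxel_mm * ((grid_shape - 1) / 2 - floor(grid_shape / 2))
  semi <- gray_axes_frac * grid_shape * voxel_mm
  u <- sweep(centers, 2, mid, "-")
  gray_vec <- (u[, 1] / semi[1])^2 + (u[, 2] / semi[2])^2 + (u[, 3] / semi[3])^2 <= 1
  gray <- array(gray_vec, dim = grid_shape)

  effect_pain <- array(0, dim = grid_shape)
  effect_nonpain <- array(0, dim = grid_shape)
  region_voxels <- vector("list", nrow(regions))
  n_voxels <- integer(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    ctr <- c(regions$x_mm[r], regions$y_mm[r], regions$z_mm[r])
    d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 +
      (centers[, 3] - ctr[3])^2
    inside <- which(d2 <= regions$radius_mm[r]^2)
    if (length(inside) == 0L) {
      abort(sprintf(
        "Region '%s' (radius %g mm at [%g, %g, %g]) covers no voxel of the grid.",
        regions$name[r], regions$radius_mm[r], ctr[1], ctr[2], ctr[3]
      ))
    }
    effect_pain[inside] <- regions$amplitude_pain[r]
    effect_nonpain[inside] <- regions$amplitude_nonpain[r]
    region_voxels[[r]] <- inside
    n_voxels[r] <- length(inside)
  }

  candidates <- setdiff(which(gray_vec), unlist(region_voxels))
  artifact_voxels <- integer(0)
  if (n_artifacts > 0) {
    if (length(candidates) < n_artifacts) {
      abort("Not enough gray voxels outside effect regions to place artifacts.")
    }
    artifact_voxels <- withr::with_seed(
      seed,
      sample(candidates, n_artifacts)
    )
    effect_pain[artifact_voxels] <- artifact_amplitude
    effect_nonpain[artifact_voxels] <- artifact_amplitude
  }

  regions <- dplyr::mutate(
    regions,
    n_voxels = n_voxels,
    sign = ifelse(.data$amplitude_pain >= .data$amplitude_nonpain, 1, -1)
  )

  structure(
    list(
      gray = gray,
      effect_pain = effect_pain,
      effect_nonpain = effect_nonpain,
      affine = affine,
      dim = grid_shape,
      voxel_mm = voxel_mm,
      regions = regions,
      region_voxels = region_voxels,
      artifact_voxels = artifact_voxels
    ),
    class = "pain_atlas"
  )
}

#' @export
print.pain_atlas <- function(x, ...) {
  cat("<pain_atlas>\n")
  cat(sprintf(
    "  grid %s at %g mm | %d gray voxels | %d regions | %d artifact voxels\n",
    paste(x$dim, collapse = "x"), x$voxel_mm, sum(x$gray),
    nrow(x$regions), length(x$artifact_voxels)
  ))
  invisible(x)
}

# linear indices of voxels in pain-predictive regions (used for recovery checks)
pain_region_voxels <- function(atlas) {
  unlist(atlas$region_voxels[atlas$regions$sign > 0])
}
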